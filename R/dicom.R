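# Minimal DICOM series I/O: explicit-VR little-endian, one single-frame
# image per file, uncompressed 16-bit pixel data. This covers exported
# SPECT and CT series as the package consumes them; multi-frame/enhanced
# objects and compressed transfer syntaxes are out of scope. Slices are
# ordered by the projection of ImagePositionPatient onto the slice normal
# (the cross product of the row and column direction cosines), which is
# robust to shuffled files and missing/unreliable InstanceNumber.

EXPLICIT_LE_UID <- "1.2.840.10008.1.2.1"

#' Read a DICOM series as a single volume
#'
#' Reads every `.dcm` file in `directory`, checks that they form one
#' single-frame series, sorts slices along the slice normal, applies
#' RescaleSlope/RescaleIntercept, and assembles the LPS affine from
#' ImageOrientationPatient, ImagePositionPatient and PixelSpacing.
#'
#' @param directory Directory containing one DICOM series.
#' @param modality Optional override; defaults to the Modality tag
#'   (`"CT"`, or `"SPECT"` for nuclear-medicine modalities).
#' @return An [image_volume()].
#' @export
read_dicom_series <- function(directory, modality = NULL) {
  files <- list.files(directory, pattern = "\\.dcm$", full.names = TRUE,
                      ignore.case = TRUE)
  if (length(files) == 0L) stop("no .dcm files found in ", directory)
  slices <- lapply(files, read_dicom_slice)
  uids <- vapply(slices, function(s) s$series_uid, character(1))
  if (length(unique(uids)) != 1L) {
    stop("directory contains more than one SeriesInstanceUID")
  }
  first <- slices[[1]]
  iop <- first$iop
  row_dir <- iop[1:3]   # direction of increasing column index
  col_dir <- iop[4:6]   # direction of increasing row index
  normal <- cross3(row_dir, col_dir)
  pos <- vapply(slices, function(s) sum(s$ipp * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0)) stop("duplicate slice positions in series")
    if (max(gaps) - min(gaps) > 1e-3) {
      stop("non-uniform slice spacing (tolerance 1e-3 mm)")
    }
  }
  dims <- c(first$cols, first$rows, nz)
  vox <- array(0, dim = dims)
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    if (s$cols != dims[1] || s$rows != dims[2]) {
      stop("inconsistent slice dimensions within series")
    }
    vox[, , k] <- s$slope * s$pixels + s$intercept
  }
  affine <- diag(4)
  affine[1:3, 1] <- row_dir * first$pixel_spacing[2]
  affine[1:3, 2] <- col_dir * first$pixel_spacing[1]
  affine[1:3, 3] <- if (nz > 1L) {
    (slices[[nz]]$ipp - slices[[1]]$ipp) / (nz - 1)
  } else {
    normal
  }
  affine[1:3, 4] <- slices[[1]]$ipp
  modality <- modality %||%
    if (identical(first$modality, "CT")) "CT" else "SPECT"
  if (modality == "SPECT") vox[vox < 0] <- 0
  image_volume(vox, affine, modality)
}

read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L ||
      rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  elems <- parse_dicom_elements(raw, 133L)
  need <- function(tag, what) {
    v <- elems[[tag]]
    if (is.null(v)) stop("missing DICOM tag ", what, " in ", path)
    v
  }
  ds <- function(x) as.numeric(strsplit(rawToChar(x), "\\\\")[[1]])
  us <- function(x) readBin(x, "integer", n = 1, size = 2, signed = FALSE,
                            endian = "little")
  rows <- us(need("0028,0010", "Rows"))
  cols <- us(need("0028,0011", "Columns"))
  bits <- us(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) stop("only 16-bit pixel data is supported: ", path)
  pixrep <- if (is.null(elems[["0028,0103"]])) 0L else us(elems[["0028,0103"]])
  px_raw <- need("7fe0,0010", "PixelData")
  pixels <- readBin(px_raw, "integer", n = rows * cols, size = 2,
                    signed = pixrep == 1L, endian = "little")
  if (length(pixels) != rows * cols) stop("truncated pixel data: ", path)
  list(
    series_uid = trimws(rawToChar(need("0020,000e", "SeriesInstanceUID"))),
    modality = trimws(rawToChar(elems[["0008,0060"]] %||% charToRaw("OT"))),
    ipp = ds(need("0020,0032", "ImagePositionPatient")),
    iop = ds(need("0020,0037", "ImageOrientationPatient")),
    pixel_spacing = ds(need("0028,0030", "PixelSpacing")),
    rows = rows, cols = cols,
    slope = if (is.null(elems[["0028,1053"]])) 1 else ds(elems[["0028,1053"]]),
    intercept = if (is.null(elems[["0028,1052"]])) 0
                else ds(elems[["0028,1052"]]),
    # pixel order on disk is row-major (column index fastest), which matches
    # a (cols, rows) array filled in R's column-major order
    pixels = matrix(pixels, nrow = cols, ncol = rows)
  )
}

# parse explicit-VR little-endian data elements into a tag-keyed list
parse_dicom_elements <- function(raw, offset) {
  elems <- list()
  n <- length(raw)
  i <- offset
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  u16 <- function(at) readBin(raw[at:(at + 1L)], "integer", size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(raw[at:(at + 3L)], "double", size = 4,
                              endian = "little")  # placeholder, replaced below
  u32 <- function(at) {
    b <- as.integer(raw[at:(at + 3L)])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  while (i + 7L <= n) {
    group <- u16(i)
    element <- u16(i + 2L)
    vr <- rawToChar(raw[(i + 4L):(i + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(i + 8L)
      hdr <- 12L
    } else {
      len <- u16(i + 6L)
      hdr <- 8L
    }
    if (len == 4294967295) stop("undefined-length DICOM elements unsupported")
    start <- i + hdr
    if (start + len - 1L > n) stop("truncated DICOM element")
    tag <- sprintf("%04x,%04x", group, element)
    elems[[tag]] <- if (len > 0L) raw[start:(start + len - 1L)] else raw(0)
    i <- start + len
  }
  elems
}

#' Write a volume as a single-frame DICOM series
#'
#' One explicit-VR little-endian file per slice, with geometry tags
#' (ImagePositionPatient, ImageOrientationPatient, PixelSpacing) derived
#' from the volume affine and intensities stored as 16-bit integers via
#' RescaleSlope/RescaleIntercept. Intended for generating test series and
#' exporting phantoms; the affine's first two columns must be orthogonal
#' to the slice direction only in the usual DICOM sense (slices are planes
#' of constant third index).
#'
#' @param vol An [image_volume()] with integer-representable intensities
#'   after rescaling.
#' @param directory Output directory (created if needed).
#' @param series_uid SeriesInstanceUID to stamp on every slice.
#' @return The directory, invisibly.
#' @export
write_dicom_series <- function(vol, directory,
                               series_uid = "1.2.826.0.1.3680043.9999.1") {
  stopifnot(inherits(vol, "image_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$voxels)
  row_dir <- vol$affine[1:3, 1] / vnorm(vol$affine[1:3, 1])
  col_dir <- vol$affine[1:3, 2] / vnorm(vol$affine[1:3, 2])
  spacing <- vol$spacing
  intercept <- if (vol$modality == "CT") -1024 else 0
  for (k in seq_len(d[3])) {
    slice <- vol$voxels[, , k]
    stored <- round(slice - intercept)
    if (any(stored < 0 | stored > 65535)) {
      stop("slice intensities outside the storable 16-bit range")
    }
    ipp <- index_to_world(vol, c(0, 0, k - 1))
    write_dicom_slice(
      file.path(directory, sprintf("slice_%04d.dcm", k)),
      pixels = stored, iop = c(row_dir, col_dir), ipp = as.numeric(ipp),
      pixel_spacing = c(spacing[2], spacing[1]),
      series_uid = series_uid, instance = k,
      modality = if (vol$modality == "CT") "CT" else "NM",
      intercept = intercept
    )
  }
  invisible(directory)
}

write_dicom_slice <- function(path, pixels, iop, ipp, pixel_spacing,
                              series_uid, instance, modality, intercept) {
  ds_fmt <- function(v) paste(sprintf("%.10g", v), collapse = "\\")
  elem_str <- function(group, element, vr, s) {
    val <- charToRaw(s)
    if (length(val) %% 2 == 1) {
      val <- c(val, if (vr == "UI") as.raw(0) else charToRaw(" "))
    }
    c(tag_raw(group, element), charToRaw(vr),
      writeBin(length(val), raw(), size = 2, endian = "little"), val)
  }
  elem_us <- function(group, element, x) {
    c(tag_raw(group, element), charToRaw("US"),
      writeBin(2L, raw(), size = 2, endian = "little"),
      writeBin(as.integer(x), raw(), size = 2, endian = "little"))
  }
  tag_raw <- function(group, element) {
    c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
      writeBin(as.integer(element), raw(), size = 2, endian = "little"))
  }
  px <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  pix_elem <- c(tag_raw(0x7fe0, 0x0010), charToRaw("OW"), raw(2),
                writeBin(length(px), raw(), size = 4, endian = "little"), px)
  sop_uid <- sprintf("%s.%d", series_uid, instance)
  body <- c(
    elem_str(0x0008, 0x0060, "CS", modality),
    elem_str(0x0020, 0x000d, "UI", paste0(series_uid, ".0")),
    elem_str(0x0020, 0x000e, "UI", series_uid),
    elem_str(0x0020, 0x0013, "IS", as.character(instance)),
    elem_str(0x0020, 0x0032, "DS", ds_fmt(ipp)),
    elem_str(0x0020, 0x0037, "DS", ds_fmt(iop)),
    elem_us(0x0028, 0x0010, nrow(t(pixels))),   # Rows
    elem_us(0x0028, 0x0011, nrow(pixels)),      # Columns
    elem_str(0x0028, 0x0030, "DS", ds_fmt(pixel_spacing)),
    elem_us(0x0028, 0x0100, 16L),               # BitsAllocated
    elem_us(0x0028, 0x0101, 16L),               # BitsStored
    elem_us(0x0028, 0x0102, 15L),               # HighBit
    elem_us(0x0028, 0x0103, 0L),                # PixelRepresentation
    elem_str(0x0028, 0x1052, "DS", ds_fmt(intercept)),
    elem_str(0x0028, 0x1053, "DS", ds_fmt(1)),
    pix_elem
  )
  # file meta group (group 0002, always explicit little endian)
  meta_body <- c(
    elem_str(0x0002, 0x0003, "UI", sop_uid),
    elem_str(0x0002, 0x0010, "UI", EXPLICIT_LE_UID)
  )
  meta_len <- c(tag_raw(0x0002, 0x0000), charToRaw("UL"),
                writeBin(4L, raw(), size = 2, endian = "little"),
                writeBin(length(meta_body), raw(), size = 4,
                         endian = "little"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_len, meta_body, body), con)
  invisible(path)
}
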