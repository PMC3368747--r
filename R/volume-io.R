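# Volume file I/O. Internally everything is an image_volume whose affine
# maps 0-based indices to DICOM patient (LPS) millimetres. NIfTI stores its
# sform in RAS, so the first two affine rows are sign-flipped on the way in
# and out (an exact operation). NRRD is written with a "left-posterior-
# superior" space field and full double precision, so NRRD round trips are
# bit-exact on the affine; NIfTI sform is float32 on disk, so round trips
# are exact only to float32 quantisation.

LPS_TO_RAS <- diag(c(-1, -1, 1, 1))

#' Read or write a volume file (NIfTI or NRRD)
#'
#' The file extension selects the format: `.nii` / `.nii.gz` (NIfTI-1, via
#' RNifti, affine stored as sform code 2) or `.nrrd` (NRRD, raw or gzip
#' encoding). Voxel data round-trip exactly; the affine round-trips exactly
#' for NRRD and to float32 precision for NIfTI.
#'
#' @param path File path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @param modality `"CT"` or `"SPECT"`, attached to the returned volume.
#' @return `read_volume()` returns an [image_volume()].
#' @export
read_volume <- function(path, modality = c("CT", "SPECT")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("volume file not found: ", path)
  ext <- volume_ext(path)
  if (ext == "nifti") {
    img <- RNifti::readNifti(path)
    vox <- as.array(img)
    attributes(vox) <- list(dim = dim(vox))
    if (length(dim(vox)) != 3L) stop("expected a 3D volume: ", path)
    sform <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                       code = NULL, imagedim = NULL)
    affine <- LPS_TO_RAS %*% matrix(as.numeric(sform), 4, 4)
    image_volume(vox, affine, modality)
  } else {
    read_nrrd(path, modality)
  }
}

#' @rdname read_volume
#' @param vol An [image_volume()] to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  ext <- volume_ext(path)
  if (ext == "nifti") {
    img <- RNifti::asNifti(vol$voxels, datatype = "double")
    sform <- LPS_TO_RAS %*% vol$affine
    RNifti::sform(img) <- structure(sform, code = 2L)
    RNifti::qform(img) <- structure(diag(4) * 0, code = 0L)
    RNifti::writeNifti(img, path)
  } else {
    write_nrrd(vol, path)
  }
  invisible(path)
}

volume_ext <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("unknown volume extension (expected .nii, .nii.gz or .nrrd): ", path)
}

# ---- NRRD ------------------------------------------------------------------

read_nrrd <- function(path, modality) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0L) stop("truncated NRRD header: ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[trimws(kv[2])]] <- kv[3]
  }
  dims <- as.integer(strsplit(trimws(fields[["sizes"]]), " +")[[1]])
  if (length(dims) != 3L) stop("expected a 3D NRRD payload: ", path)
  dirs <- parse_nrrd_vectors(fields[["space directions"]])
  origin <- parse_nrrd_vector(fields[["space origin"]])
  space <- tolower(fields[["space"]] %||% "left-posterior-superior")
  affine <- diag(4)
  affine[1:3, 1:3] <- dirs
  affine[1:3, 4] <- origin
  if (space %in% c("right-anterior-superior", "ras")) {
    affine <- LPS_TO_RAS %*% affine
  } else if (!space %in% c("left-posterior-superior", "lps")) {
    stop("unsupported NRRD space: ", space)
  }
  type <- fields[["type"]]
  enc <- fields[["encoding"]]
  n <- prod(dims)
  payload <- readBin(con, "raw", n = 8 * n + 1024)
  if (identical(enc, "gzip")) payload <- memDecompress(payload, type = "gzip")
  vals <- switch(type,
    "double" = readBin(payload, "double", n = n, size = 8, endian = "little"),
    "float"  = readBin(payload, "double", n = n, size = 4, endian = "little"),
    "short"  = readBin(payload, "integer", n = n, size = 2, signed = TRUE,
                       endian = "little"),
    "int"    = readBin(payload, "integer", n = n, size = 4, endian = "little"),
    stop("unsupported NRRD type: ", type)
  )
  if (length(vals) != n) stop("truncated NRRD payload: ", path)
  image_volume(array(as.numeric(vals), dim = dims), affine, modality)
}

write_nrrd <- function(vol, path) {
  dirs <- vol$affine[1:3, 1:3]
  origin <- vol$affine[1:3, 4]
  fmt <- function(v) paste0("(", paste(sprintf("%.17g", v), collapse = ","), ")")
  header <- c(
    "NRRD0004",
    "# orthospect volume",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    paste("sizes:", paste(dim(vol$voxels), collapse = " ")),
    paste("space directions:", fmt(dirs[, 1]), fmt(dirs[, 2]), fmt(dirs[, 3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: gzip",
    paste("space origin:", fmt(origin)),
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  raw <- writeBin(as.numeric(vol$voxels), raw(), size = 8, endian = "little")
  writeBin(memCompress(raw, type = "gzip"), con)
  invisible(path)
}

parse_nrrd_vector <- function(s) {
  as.numeric(strsplit(gsub("[()]", "", trimws(s)), ",")[[1]])
}

parse_nrrd_vectors <- function(s) {
  parts <- regmatches(s, gregexpr("\\([^)]*\\)", s))[[1]]
  if (length(parts) != 3L) stop("expected 3 space directions")
  do.call(cbind, lapply(parts, parse_nrrd_vector))
}
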