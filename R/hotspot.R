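#' Rectangular selection box for hotspot analysis
#'
#' A rectangular volume selector: thin wrapper around
#' [reference_region()] that additionally checks the box intersects at
#' least one voxel centre of the given SPECT volume.
#'
#' @param spect A SPECT [image_volume()].
#' @param min,max Length-3 box corners, mm, in `frame_tag` coordinates.
#' @param frame_tag `"world"`, `"femoral"` or `"tibial"`.
#' @param frame An `anatomic_frame`, required for anatomical `frame_tag`s.
#' @return A [reference_region()].
#' @export
select_box <- function(spect, min, max, frame_tag = "world", frame = NULL) {
  region <- reference_region(min, max, frame_tag)
  if (!any(region_membership(spect, region, frame))) {
    stop("selection box does not intersect the volume")
  }
  region
}

#' Threshold-based hotspot mask within a region
#'
#' Marks every voxel whose centre lies in the region and whose intensity
#' is at or above the threshold (inclusive, so boundary behaviour is
#' deterministic). Thresholding replaces explicit segmentation: with a
#' clinically calibrated threshold it distinguishes altered tracer uptake
#' from background.
#'
#' @param spect A SPECT [image_volume()].
#' @param region A [reference_region()] (e.g. from [select_box()]).
#' @param threshold_raw Threshold in raw intensity units (e.g. from
#'   [threshold_from_model()] or [max_fraction_threshold()]).
#' @param frame An `anatomic_frame` when the region needs one.
#' @return An object of class `voxel_mask`: logical array `bits` congruent
#'   with the volume, plus the parent affine.
#' @export
hotspot_mask <- function(spect, region, threshold_raw, frame = NULL) {
  stopifnot(inherits(spect, "image_volume"), is.numeric(threshold_raw))
  inside <- region_membership(spect, region, frame)
  if (!any(inside)) stop("region does not intersect the volume")
  bits <- array(inside & as.numeric(spect$voxels) >= threshold_raw,
                dim = dim(spect$voxels))
  voxel_mask(bits, spect)
}

#' Voxel mask congruent with a parent volume
#'
#' @param bits Logical 3D array, same shape as the parent volume.
#' @param parent The parent [image_volume()] (geometry reference).
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(bits, parent) {
  stopifnot(inherits(parent, "image_volume"))
  if (!identical(dim(bits), dim(parent$voxels))) {
    stop("mask shape must equal the parent volume shape")
  }
  structure(list(bits = array(as.logical(bits), dim = dim(bits)),
                 affine = parent$affine, spacing = parent$spacing),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask %s, %d voxels set>\n",
              paste(dim(x$bits), collapse = "x"), sum(x$bits)))
  invisible(x)
}

#' Fraction-of-maximum threshold
#'
#' The conventional non-normalised threshold: a fraction of the global
#' maximum intensity (e.g. 0.9 or 0.6). Such thresholds depend on the
#' patient's overall uptake and on the hottest voxel, which is precisely
#' the comparability problem reference-region normalisation removes.
#'
#' @param spect A SPECT [image_volume()].
#' @param fraction Scalar in (0, 1].
#' @return Threshold in raw intensity units.
#' @export
max_fraction_threshold <- function(spect, fraction) {
  stopifnot(inherits(spect, "image_volume"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  mx <- max(spect$voxels)
  if (mx <= 0) stop("volume has no positive intensities to threshold")
  fraction * mx
}

#' 26-connectivity connected components of a mask
#'
#' Labels the mask's connected components under 26-connectivity (voxels
#' sharing a face, edge or corner). Labels are deterministic: component 1
#' has the most voxels, ties broken by smallest linear voxel index.
#'
#' @param mask A [voxel_mask()].
#' @return List with `labels` (integer array, 0 = background), `count`
#'   (number of components) and `sizes` (voxel counts, descending).
#' @export
connected_components <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  d <- dim(mask$bits)
  labels <- array(0L, dim = d)
  idx_set <- which(mask$bits)
  if (length(idx_set) == 0L) {
    return(list(labels = labels, count = 0L, sizes = integer(0)))
  }
  # precompute 26-neighbourhood index offsets (validity checked per axis)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  ijk <- arrayInd(idx_set, d)
  in_mask <- mask$bits
  next_label <- 0L
  comp_sizes <- integer(0)
  comp_minidx <- integer(0)
  for (s in seq_along(idx_set)) {
    start <- idx_set[s]
    if (labels[start] != 0L) next
    next_label <- next_label + 1L
    queue <- start
    labels[start] <- next_label
    size <- 0L
    while (length(queue) > 0L) {
      cur <- queue
      queue <- integer(0)
      size <- size + length(cur)
      cijk <- arrayInd(cur, d)
      for (o in seq_len(nrow(offs))) {
        nb <- cijk + matrix(offs[o, ], nrow(cijk), 3, byrow = TRUE)
        ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
              nb[, 2] >= 1L & nb[, 2] <= d[2] &
              nb[, 3] >= 1L & nb[, 3] <= d[3]
        if (!any(ok)) next
        nbl <- (nb[ok, 3, drop = TRUE] - 1L) * (d[1] * d[2]) +
               (nb[ok, 2, drop = TRUE] - 1L) * d[1] + nb[ok, 1, drop = TRUE]
        nbl <- nbl[in_mask[nbl] & labels[nbl] == 0L]
        if (length(nbl) > 0L) {
          nbl <- unique(nbl)
          labels[nbl] <- next_label
          queue <- c(queue, nbl)
        }
      }
    }
    comp_sizes <- c(comp_sizes, size)
    comp_minidx <- c(comp_minidx, start)
  }
  # relabel: descending size, ties by smallest linear index
  ord <- order(-comp_sizes, comp_minidx)
  remap <- integer(next_label)
  remap[ord] <- seq_len(next_label)
  labels[labels > 0L] <- remap[labels[labels > 0L]]
  list(labels = labels, count = next_label, sizes = comp_sizes[ord])
}

#' Volumetric hotspot metrics
#'
#' Quantifies a thresholded uptake region: voxel count, physical volume,
#' normalised maximum and mean intensity (uptake ratios under the given
#' model), intensity-weighted centroid in anatomic coordinates, Welch
#' t-statistic of the masked intensities against the reference
#' distribution, and the number of 26-connected components.
#'
#' @param spect A SPECT [image_volume()].
#' @param mask A [voxel_mask()] over `spect`.
#' @param model A [normalization_model()].
#' @param frame An `anatomic_frame` for centroid reporting (`NULL` reports
#'   the centroid in world coordinates).
#' @param ref The reference-region `intensity_stats` (defaults to
#'   `model$ref`).
#' @param threshold_raw Optional raw threshold to record in the output.
#' @param weighted Intensity-weighted centroid (default) or unweighted.
#' @return An object of class `hotspot_metrics`; when the mask is empty all
#'   intensity metrics are `NA` and `defined` is `FALSE`.
#' @export
hotspot_metrics <- function(spect, mask, model, frame = NULL, ref = NULL,
                            threshold_raw = NA_real_, weighted = TRUE) {
  stopifnot(inherits(spect, "image_volume"), inherits(mask, "voxel_mask"),
            inherits(model, "normalization_model"))
  if (!identical(dim(mask$bits), dim(spect$voxels))) {
    stop("mask and volume shapes differ")
  }
  ref <- ref %||% model$ref
  count <- sum(mask$bits)
  voxvol <- voxel_volume_mm3(spect)
  if (count == 0L) {
    return(structure(
      list(defined = FALSE, voxel_count = 0L, volume_mm3 = 0,
           volume_ml = 0, max_ratio = NA_real_, mean_ratio = NA_real_,
           centroid_anatomic = rep(NA_real_, 3), threshold_raw = threshold_raw,
           t = NA_real_, df = NA_real_, p = NA_real_,
           component_count = 0L),
      class = "hotspot_metrics"
    ))
  }
  vals <- as.numeric(spect$voxels)[as.logical(mask$bits)]
  idx <- which(mask$bits)
  ijk <- arrayInd(idx, dim(spect$voxels)) - 1L
  centres <- index_to_world(spect, ijk)
  w <- if (weighted) vals else rep(1, length(vals))
  if (sum(w) <= 0) w <- rep(1, length(vals))
  centroid_world <- colSums(centres * w) / sum(w)
  centroid <- if (is.null(frame)) centroid_world else
    world_to_anatomic(centroid_world, frame)
  tt <- if (count >= 2L && ref$n >= 2L) {
    hotspot_vs_reference_test(intensity_stats(vals), ref)
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_)
  }
  cc <- connected_components(mask)
  structure(
    list(defined = TRUE, voxel_count = as.integer(count),
         volume_mm3 = count * voxvol, volume_ml = count * voxvol / 1000,
         max_ratio = normalize_intensity(max(vals), model),
         mean_ratio = normalize_intensity(mean(vals), model),
         centroid_anatomic = as.numeric(centroid),
         threshold_raw = threshold_raw,
         t = tt$t, df = tt$df, p = tt$p,
         component_count = cc$count),
    class = "hotspot_metrics"
  )
}

#' @export
print.hotspot_metrics <- function(x, ...) {
  if (!x$defined) {
    cat("<hotspot_metrics: empty mask (no voxels above threshold)>\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "<hotspot_metrics: %d voxels, %.1f mm^3 (%.3f mL), max ratio %.3g, ",
    "mean ratio %.3g,\n  centroid (%s) mm, t=%.3g p=%.3g, %d component(s)>\n"),
    x$voxel_count, x$volume_mm3, x$volume_ml, x$max_ratio, x$mean_ratio,
    paste(signif(x$centroid_anatomic, 4), collapse = ", "),
    x$t, x$p, x$component_count))
  invisible(x)
}

#' Export a voxel mask as a NIfTI volume
#'
#' @param mask A [voxel_mask()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- image_volume(array(as.numeric(mask$bits), dim = dim(mask$bits)),
                      mask$affine, "SPECT")
  write_volume(vol, path)
}
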