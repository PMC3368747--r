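#' Resample a volume into an anatomical reference frame
#'
#' Produces a new volume whose grid axes are aligned with the frame's
#' (ML, AP, PROX) axes, covering the axis-aligned box `bounds` (given in
#' frame coordinates, mm) at the requested spacing. Values are trilinearly
#' interpolated from the input (nearest-neighbour available for masks);
#' samples outside the input extent read as air (-1024) for CT and as zero
#' counts for SPECT. The output affine embeds the frame grid back into
#' world coordinates, so frame coordinates of output voxel (i,j,k) are
#' `bounds$min + c(i,j,k) * spacing`.
#'
#' @param vol An [image_volume()].
#' @param frame An `anatomic_frame` (axes must be orthonormal).
#' @param spacing Length-3 voxel spacing in mm (or scalar, recycled).
#' @param bounds List with `min` and `max` length-3 frame-coordinate bounds.
#' @param interp `"linear"` (default) or `"nearest"`.
#' @param fill Out-of-extent fill value; default by modality.
#' @return An [image_volume()] on the frame-aligned grid.
#' @export
resample_to_frame <- function(vol, frame, spacing, bounds,
                              interp = c("linear", "nearest"), fill = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(frame, "anatomic_frame"))
  interp <- match.arg(interp)
  check_orthonormal(frame$axes)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  lo <- as.numeric(bounds$min)
  hi <- as.numeric(bounds$max)
  if (length(lo) != 3L || length(hi) != 3L || any(hi - lo <= 0)) {
    stop("bounds must be a non-degenerate box (min < max componentwise)")
  }
  n <- pmax(1L, as.integer(floor((hi - lo) / spacing + 1e-9)) + 1L)
  i <- rep.int(seq_len(n[1]) - 1, n[2] * n[3])
  j <- rep.int(rep(seq_len(n[2]) - 1, each = n[1]), n[3])
  k <- rep(seq_len(n[3]) - 1, each = n[1] * n[2])
  fpts <- cbind(lo[1] + i * spacing[1],
                lo[2] + j * spacing[2],
                lo[3] + k * spacing[3])
  wpts <- anatomic_to_world(fpts, frame)
  vals <- sample_volume(vol, wpts, interp = interp, fill = fill)
  affine <- diag(4)
  affine[1:3, 1:3] <- t(frame$axes) %*% diag(spacing)
  affine[1:3, 4] <- anatomic_to_world(lo, frame)
  image_volume(array(vals, dim = n), affine, vol$modality)
}
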