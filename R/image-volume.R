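#' 3D image volume with world-coordinate geometry
#'
#' The basic container for a co-registered SPECT/CT pair: a 3D scalar array
#' plus a 4x4 affine matrix mapping 0-based voxel indices to world
#' millimetres in the DICOM patient (LPS) convention. The affine uses the
#' index-centre convention: index (0,0,0) maps to the centre of the first
#' voxel. CT volumes hold Hounsfield-like units, SPECT volumes hold
#' non-negative tracer counts.
#'
#' @param voxels A numeric 3D array.
#' @param affine A 4x4 invertible homogeneous matrix, voxel index to world mm.
#' @param modality Either `"CT"` or `"SPECT"`.
#' @return An object of class `image_volume` with fields `voxels`, `affine`,
#'   `modality` and derived `spacing` (mm along each index axis).
#' @export
image_volume <- function(voxels, affine, modality = c("CT", "SPECT")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("voxels must be a 3D array")
  }
  if (any(dim(voxels) < 1L)) stop("all volume dimensions must be >= 1")
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L))) {
    stop("affine must be a 4x4 matrix")
  }
  if (abs(det(affine)) < .Machine$double.eps * 100) {
    stop("affine must be invertible")
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  if (modality == "SPECT" && any(voxels < 0, na.rm = TRUE)) {
    stop("SPECT voxel values must be non-negative")
  }
  structure(
    list(voxels = voxels, affine = affine, modality = modality,
         spacing = spacing),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume %s %s, spacing %s mm, range [%g, %g]>\n",
              x$modality, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

# physical volume of one voxel in mm^3 (|det| of the linear part)
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Map voxel indices to world coordinates
#'
#' @param vol An [image_volume()].
#' @param idx An n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return An n x 3 matrix of world (LPS) coordinates in mm.
#' @export
index_to_world <- function(vol, idx) {
  idx <- rbind_pts(idx)
  t(vol$affine[1:3, 1:3] %*% t(idx) + vol$affine[1:3, 4])
}

#' Map world coordinates to (fractional, 0-based) voxel indices
#'
#' @param vol An [image_volume()].
#' @param pts An n x 3 matrix of world coordinates in mm.
#' @return An n x 3 matrix of continuous 0-based voxel indices.
#' @export
world_to_index <- function(vol, pts) {
  pts <- rbind_pts(pts)
  inv <- solve(vol$affine)
  t(inv[1:3, 1:3] %*% t(pts) + inv[1:3, 4])
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3L, byrow = TRUE)
  storage.mode(p) <- "double"
  p
}

# world coordinates of every voxel centre, in array (column-major) order
voxel_centre_grid <- function(vol) {
  d <- dim(vol$voxels)
  i <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  index_to_world(vol, cbind(i, j, k))
}

#' Trilinear (or nearest-neighbour) sampling of a volume at world points
#'
#' Points outside the volume extent evaluate to `fill`.
#'
#' @param vol An [image_volume()].
#' @param pts n x 3 matrix of world-mm points.
#' @param interp `"linear"` or `"nearest"`.
#' @param fill Value for points outside the grid; defaults to -1024 for CT
#'   (air) and 0 for SPECT (no counts).
#' @return Numeric vector of sampled intensities, length n.
#' @export
sample_volume <- function(vol, pts, interp = c("linear", "nearest"),
                          fill = NULL) {
  interp <- match.arg(interp)
  fill <- fill %||% if (vol$modality == "CT") -1024 else 0
  g <- world_to_index(vol, pts)
  d <- dim(vol$voxels)
  out <- rep.int(as.numeric(fill), nrow(g))
  if (interp == "nearest") {
    gi <- round(g)
    ok <- gi[, 1] >= 0 & gi[, 1] <= d[1] - 1 &
          gi[, 2] >= 0 & gi[, 2] <= d[2] - 1 &
          gi[, 3] >= 0 & gi[, 3] <= d[3] - 1
    if (any(ok)) {
      out[ok] <- vol$voxels[gi[ok, , drop = FALSE] + 1]
    }
    return(out)
  }
  ok <- g[, 1] >= 0 & g[, 1] <= d[1] - 1 &
        g[, 2] >= 0 & g[, 2] <= d[2] - 1 &
        g[, 3] >= 0 & g[, 3] <= d[3] - 1
  if (!any(ok)) return(out)
  gg <- g[ok, , drop = FALSE]
  # lower corner, clamped so fractional weight stays in [0,1] at the far face
  i0 <- pmin(floor(gg), rep(d - 2L, each = nrow(gg)))
  i0 <- pmax(i0, 0)
  f <- gg - i0
  v <- vol$voxels
  gather <- function(dx, dy, dz) {
    v[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)]
  }
  w000 <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3])
  w100 <- f[, 1] * (1 - f[, 2]) * (1 - f[, 3])
  w010 <- (1 - f[, 1]) * f[, 2] * (1 - f[, 3])
  w110 <- f[, 1] * f[, 2] * (1 - f[, 3])
  w001 <- (1 - f[, 1]) * (1 - f[, 2]) * f[, 3]
  w101 <- f[, 1] * (1 - f[, 2]) * f[, 3]
  w011 <- (1 - f[, 1]) * f[, 2] * f[, 3]
  w111 <- f[, 1] * f[, 2] * f[, 3]
  out[ok] <- w000 * gather(0, 0, 0) + w100 * gather(1, 0, 0) +
    w010 * gather(0, 1, 0) + w110 * gather(1, 1, 0) +
    w001 * gather(0, 0, 1) + w101 * gather(1, 0, 1) +
    w011 * gather(0, 1, 1) + w111 * gather(1, 1, 1)
  out
}
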