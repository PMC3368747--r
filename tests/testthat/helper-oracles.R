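# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by the most direct route available (loops, enumeration,
# closed forms) and stays independent of the package code paths it checks.

# per-voxel triple-loop region statistics (world-frame axis-aligned box)
brute_region_stats <- function(vol, region) {
  vals <- c()
  d <- dim(vol$voxels)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        p <- as.numeric(vol$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
        if (all(p >= region$min) && all(p < region$max)) {
          vals <- c(vals, vol$voxels[i, j, k])
        }
      }
    }
  }
  list(n = length(vals),
       mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) >= 2) sd(vals) else NA_real_,
       min = if (length(vals)) min(vals) else NA_real_,
       max = if (length(vals)) max(vals) else NA_real_)
}

# per-voxel triple-loop threshold mask
brute_hotspot_mask <- function(vol, region, threshold) {
  d <- dim(vol$voxels)
  bits <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) {
    for (j in seq_len(d[2])) {
      for (i in seq_len(d[1])) {
        p <- as.numeric(vol$affine %*% c(i - 1, j - 1, k - 1, 1))[1:3]
        if (all(p >= region$min) && all(p < region$max) &&
            vol$voxels[i, j, k] >= threshold) {
          bits[i, j, k] <- TRUE
        }
      }
    }
  }
  bits
}

# recursive-style flood fill (explicit stack, 26-connectivity) counting
# components; independent of the package's queue/label implementation
flood_fill_components <- function(bits) {
  d <- dim(bits)
  seen <- array(FALSE, dim = d)
  sizes <- integer(0)
  for (start in which(bits)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      ci <- arrayInd(cur, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        ni <- ci + c(dx, dy, dz)
        if (any(ni < 1) || any(ni > d)) next
        lin <- (ni[3] - 1) * d[1] * d[2] + (ni[2] - 1) * d[1] + ni[1]
        if (bits[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          stack <- c(stack, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# rotation angle via an independent quaternion conversion
quaternion_angle_deg <- function(R) {
  tr <- sum(diag(R))
  qw <- sqrt(max(0, 1 + tr)) / 2
  qv <- sqrt(pmax(0, c(1 + R[1, 1] - R[2, 2] - R[3, 3],
                       1 - R[1, 1] + R[2, 2] - R[3, 3],
                       1 - R[1, 1] - R[2, 2] + R[3, 3]))) / 2
  2 * atan2(sqrt(sum(qv^2)), abs(qw)) * 180 / pi
}

# uniform random rotation from a normalised Gaussian quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# random anatomically plausible landmark set: epicondyles ~80 mm apart,
# head ~400 mm proximal with coronal/sagittal obliquity, talus distal,
# everything under a random rigid pose
random_landmarks <- function(with_talus = TRUE) {
  R <- random_rotation()
  t <- runif(3, -200, 200)
  sep <- runif(1, 60, 100)
  med <- c(-sep / 2, rnorm(1, 0, 3), rnorm(1, 0, 3))
  lat <- c(sep / 2, rnorm(1, 0, 3), rnorm(1, 0, 3))
  head <- c(runif(1, -60, 60), runif(1, -40, 40), runif(1, 330, 450))
  talus <- c(runif(1, -30, 30), runif(1, -30, 30), -runif(1, 300, 400))
  pose <- function(p) as.numeric(R %*% p + t)
  landmark_set(
    medial_epicondyle = pose(med), lateral_epicondyle = pose(lat),
    femoral_head_centre = pose(head),
    talus_centre = if (with_talus) pose(talus) else NULL,
    side = sample(c("left", "right"), 1)
  )
}

# apply a rigid transform to every point of a landmark set
transform_landmarks <- function(lm, R, t) {
  landmark_set(
    medial_epicondyle = as.numeric(R %*% lm$medial_epicondyle + t),
    lateral_epicondyle = as.numeric(R %*% lm$lateral_epicondyle + t),
    femoral_head_centre = as.numeric(R %*% lm$femoral_head_centre + t),
    talus_centre = if (is.null(lm$talus_centre)) NULL else
      as.numeric(R %*% lm$talus_centre + t),
    side = lm$side
  )
}
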