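#' Reference region: an axis-aligned box in a chosen frame
#'
#' A clinically neutral region (canonically a box spanning the middle of
#' the femoral shaft, away from the articular surfaces) whose SPECT
#' intensity distribution calibrates all normalised measurements. The box
#' is axis-aligned in either world coordinates (`frame_tag = "world"`) or
#' an anatomical frame (`"femoral"` / `"tibial"`); a voxel belongs to the
#' region when its centre, mapped into that frame, lies in the half-open
#' box `[min, max)` (half-open so adjacent boxes never double count).
#'
#' @param min,max Length-3 box corners in frame coordinates, mm.
#' @param frame_tag `"world"`, `"femoral"` or `"tibial"`.
#' @return An object of class `reference_region`.
#' @export
reference_region <- function(min, max, frame_tag = c("world", "femoral",
                                                     "tibial")) {
  frame_tag <- match.arg(frame_tag)
  min <- as.numeric(min)
  max <- as.numeric(max)
  stopifnot(length(min) == 3L, length(max) == 3L)
  if (any(max - min <= 0)) {
    stop("region must have min < max componentwise (positive box volume)")
  }
  structure(list(min = min, max = max, frame_tag = frame_tag),
            class = "reference_region")
}

# default mid-femoral-shaft reference region: 150-200 mm proximal to the
# knee centre along the mechanical axis, full bone cross-section
default_reference_region <- function(half_width = 25) {
  reference_region(min = c(-half_width, -half_width, 150),
                   max = c(half_width, half_width, 200),
                   frame_tag = "femoral")
}

# logical vector (in array order) marking voxels whose centre falls in the
# half-open region box
region_membership <- function(vol, region, frame = NULL) {
  stopifnot(inherits(vol, "image_volume"), inherits(region, "reference_region"))
  pts <- voxel_centre_grid(vol)
  if (region$frame_tag != "world") {
    if (is.null(frame)) {
      stop("region is defined in the ", region$frame_tag,
           " frame; an anatomic frame is required")
    }
    pts <- world_to_anatomic(pts, frame)
  }
  pts[, 1] >= region$min[1] & pts[, 1] < region$max[1] &
    pts[, 2] >= region$min[2] & pts[, 2] < region$max[2] &
    pts[, 3] >= region$min[3] & pts[, 3] < region$max[3]
}

#' Intensity distribution statistics of a region
#'
#' Summarises the SPECT (or CT) intensities of all voxels whose centres lie
#' inside the region: count, mean, sample standard deviation (n-1
#' denominator), min, max, and a histogram.
#'
#' @param vol An [image_volume()].
#' @param region A [reference_region()].
#' @param frame An `anatomic_frame`, required when the region is defined in
#'   an anatomical frame.
#' @param breaks Histogram bin edges, or a bin count over the value range.
#' @return An object of class `intensity_stats` with fields `n`, `mean`,
#'   `sd`, `min`, `max`, `histogram` (list of `breaks`, `counts`).
#' @export
region_stats <- function(vol, region, frame = NULL, breaks = 64) {
  inside <- region_membership(vol, region, frame)
  if (!any(inside)) stop("region does not intersect the volume")
  intensity_stats(as.numeric(vol$voxels)[inside], breaks = breaks)
}

intensity_stats <- function(values, breaks = 64) {
  n <- length(values)
  stopifnot(n >= 1L)
  if (length(breaks) == 1L) {
    rng <- range(values)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = breaks + 1L)
  }
  counts <- hist_counts(values, breaks)
  structure(
    list(n = n, mean = mean(values), sd = if (n >= 2L) stats::sd(values)
         else NA_real_,
         min = min(values), max = max(values),
         histogram = list(breaks = breaks, counts = counts)),
    class = "intensity_stats"
  )
}

# half-open bins [b_i, b_{i+1}), last bin closed above
hist_counts <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE,
                      all.inside = FALSE)
  idx[idx < 1L | idx > length(breaks) - 1L] <- NA_integer_
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' @export
print.intensity_stats <- function(x, ...) {
  cat(sprintf("<intensity_stats n=%d mean=%.4g sd=%.4g range=[%.4g, %.4g]>\n",
              x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Intensity normalisation model from a reference region
#'
#' Converts raw SPECT intensities into normalised values using the
#' reference-region distribution. Three modes are offered; which best
#' correlates with clinical outcome is an open question, so none is
#' canonical:
#' * `scale_by_mean`: value / reference mean (a dimensionless uptake ratio;
#'   the form in which hotspot maxima are conventionally reported),
#' * `offset_by_mean`: value - reference mean,
#' * `zscore`: (value - reference mean) / reference sd.
#'
#' @param ref An `intensity_stats` object for the reference region.
#' @param mode One of `"scale_by_mean"`, `"offset_by_mean"`, `"zscore"`.
#' @return An object of class `normalization_model`.
#' @export
normalization_model <- function(ref, mode = c("scale_by_mean",
                                              "offset_by_mean", "zscore")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "intensity_stats"))
  if (mode == "scale_by_mean" && ref$mean <= 0) {
    stop("scale_by_mean requires a positive reference mean")
  }
  if (mode == "zscore" && (is.na(ref$sd) || ref$sd <= 0)) {
    stop("zscore requires a positive reference sd")
  }
  structure(list(mode = mode, ref = ref), class = "normalization_model")
}

#' Normalise intensities against the reference region
#'
#' Applies the model to a scalar, vector, or voxelwise to an
#' [image_volume()] (which is returned with normalised voxels and the same
#' geometry).
#'
#' @param value Numeric value(s) or an [image_volume()].
#' @param model A [normalization_model()].
#' @return Normalised value(s) or volume.
#' @export
normalize_intensity <- function(value, model) {
  stopifnot(inherits(model, "normalization_model"))
  if (inherits(value, "image_volume")) {
    vox <- normalize_intensity(value$voxels, model)
    out <- value
    out$voxels <- vox
    # offset/zscore modes can produce negative values; keep them (the
    # volume is no longer raw counts)
    return(out)
  }
  m <- model$ref$mean
  switch(model$mode,
    scale_by_mean = value / m,
    offset_by_mean = value - m,
    zscore = (value - m) / model$ref$sd
  )
}

#' Raw-intensity threshold from a normalisation model
#'
#' Two threshold families: `k_times_mean` (k times the reference-region
#' mean; k = 3 marks a clinically relevant uptake level, k = 4 a stricter
#' focus on the hotspot core) and `n_sd` (mean plus n reference standard
#' deviations).
#'
#' @param model A [normalization_model()].
#' @param rule A list, either `list(k_times_mean = k)` with k > 0 or
#'   `list(n_sd = n)` with n >= 0.
#' @return The threshold in raw intensity units.
#' @export
threshold_from_model <- function(model, rule) {
  stopifnot(inherits(model, "normalization_model"), is.list(rule))
  ref <- model$ref
  if (!is.null(rule$k_times_mean)) {
    k <- rule$k_times_mean
    if (!is.numeric(k) || k <= 0) stop("k_times_mean requires k > 0")
    return(k * ref$mean)
  }
  if (!is.null(rule$n_sd)) {
    n <- rule$n_sd
    if (!is.numeric(n) || n < 0) stop("n_sd requires n >= 0")
    if (is.na(ref$sd)) stop("n_sd rule requires a reference sd (n >= 2 voxels)")
    return(ref$mean + n * ref$sd)
  }
  stop("rule must contain k_times_mean or n_sd")
}

#' Welch t-test between hotspot and reference distributions
#'
#' Compares the intensity distribution of a hotspot against the reference
#' region using Welch's unequal-variance two-sample t-statistic computed
#' from the summary statistics, with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value.
#'
#' @param hot,ref `intensity_stats` objects with `n >= 2`.
#' @return List with `t`, `df` and `p`.
#' @export
hotspot_vs_reference_test <- function(hot, ref) {
  stopifnot(inherits(hot, "intensity_stats"), inherits(ref, "intensity_stats"))
  if (hot$n < 2L || ref$n < 2L) {
    stop("both samples need n >= 2 for the t-test")
  }
  a <- hot$sd^2 / hot$n
  b <- ref$sd^2 / ref$n
  se <- sqrt(a + b)
  if (se == 0) {
    # both distributions are constant
    if (hot$mean == ref$mean) {
      return(list(t = 0, df = hot$n + ref$n - 2, p = 1))
    }
    return(list(t = sign(hot$mean - ref$mean) * Inf, df = hot$n + ref$n - 2,
                p = 0))
  }
  t <- (hot$mean - ref$mean) / se
  df <- (a + b)^2 / (a^2 / (hot$n - 1) + b^2 / (ref$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Global / reference ("saved") / ROI ("local") histogram triplet
#'
#' The three histograms that contextualise a region of interest: the whole
#' dataset ("global"), the reference region ("saved") and the ROI
#' ("local"), all on shared bin edges spanning `[0, global max]` so the
#' distributions are directly comparable.
#'
#' @param spect A SPECT [image_volume()].
#' @param ref_region,roi [reference_region()] objects.
#' @param frame An `anatomic_frame` when either region needs one.
#' @param nbins Number of shared uniform bins.
#' @return List of three `list(breaks, counts)` histograms: `global`,
#'   `saved`, `local`, plus the shared `breaks`.
#' @export
histogram_triplet <- function(spect, ref_region, roi, frame = NULL,
                              nbins = 64) {
  stopifnot(inherits(spect, "image_volume"))
  vals <- as.numeric(spect$voxels)
  breaks <- seq(0, max(vals), length.out = nbins + 1L)
  if (max(vals) <= 0) breaks <- seq(0, 1, length.out = nbins + 1L)
  inside_ref <- region_membership(spect, ref_region, frame)
  inside_roi <- region_membership(spect, roi, frame)
  if (!any(inside_ref)) stop("reference region does not intersect the volume")
  if (!any(inside_roi)) stop("ROI does not intersect the volume")
  list(
    breaks = breaks,
    global = list(breaks = breaks, counts = hist_counts(vals, breaks)),
    saved = list(breaks = breaks, counts = hist_counts(vals[inside_ref],
                                                       breaks)),
    local = list(breaks = breaks, counts = hist_counts(vals[inside_roi],
                                                       breaks))
  )
}
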