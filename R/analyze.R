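# End-to-end pipeline: landmarks -> frames -> reference-region statistics
# -> normalisation -> hotspot segmentation & metrics -> histograms & meshes.
# The CLI (inst/cli/orthospect) is a thin wrapper over these functions.

#' Analysis configuration
#'
#' Assembles and validates the configuration for [run_analyze()]. A config
#' can also be read from a YAML (canonical) or JSON file with
#' [read_config()]; keys match the argument names.
#'
#' @param ct,spect Paths to the CT and SPECT volumes (NIfTI/NRRD files, or
#'   directories containing DICOM series).
#' @param landmarks Path to the landmark JSON file.
#' @param out_dir Output directory for artifacts.
#' @param reference_region List with `min`, `max` (mm) and `frame`
#'   (`"world"`, `"femoral"`, `"tibial"`); default mid-femoral-shaft box,
#'   150-200 mm proximal to the knee centre.
#' @param normalization `"scale_by_mean"`, `"offset_by_mean"` or
#'   `"zscore"`.
#' @param threshold Threshold rule: `list(k_times_mean = k)`,
#'   `list(n_sd = n)` or `list(max_fraction = f)`.
#' @param roi Region-of-interest box, same shape as `reference_region`;
#'   default a box around the knee in the femoral frame.
#' @param mesh List with `enabled` and `bone_level` (HU, default +150).
#' @param seed Integer seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(ct, spect, landmarks, out_dir,
                            reference_region = list(min = c(-25, -25, 150),
                                                    max = c(25, 25, 200),
                                                    frame = "femoral"),
                            normalization = "scale_by_mean",
                            threshold = list(k_times_mean = 3),
                            roi = list(min = c(-60, -60, -40),
                                       max = c(60, 60, 60),
                                       frame = "femoral"),
                            mesh = list(enabled = TRUE, bone_level = 150),
                            seed = 1L) {
  cfg <- list(ct = ct, spect = spect, landmarks = landmarks,
              out_dir = out_dir, reference_region = reference_region,
              normalization = normalization, threshold = threshold,
              roi = roi, mesh = mesh, seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  for (key in c("ct", "spect", "landmarks", "out_dir")) {
    if (is.null(cfg[[key]])) stop("config error: '", key, "' is required")
  }
  rule <- cfg$threshold
  known <- c("k_times_mean", "n_sd", "max_fraction")
  if (!is.list(rule) || sum(names(rule) %in% known) != 1L) {
    stop("config error: threshold must be exactly one of k_times_mean, ",
         "n_sd or max_fraction")
  }
  if (!cfg$normalization %in% c("scale_by_mean", "offset_by_mean",
                                "zscore")) {
    stop("config error: unknown normalization mode '", cfg$normalization,
         "'")
  }
  for (box in list(cfg$reference_region, cfg$roi)) {
    if (length(box$min) != 3L || length(box$max) != 3L ||
        any(unlist(box$max) - unlist(box$min) <= 0)) {
      stop("config error: region boxes need min < max componentwise")
    }
  }
  invisible(cfg)
}

#' Read an analysis config from YAML or JSON
#'
#' @param path Config file (`.yaml`/`.yml` canonical, `.json` accepted).
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(analysis_config, raw)
}

load_volume_input <- function(path, modality) {
  if (dir.exists(path)) {
    read_dicom_series(path, modality = modality)
  } else {
    read_volume(path, modality = modality)
  }
}

region_from_cfg <- function(box) {
  tag <- box$frame %||% "world"
  if (tag == "anatomic") tag <- "femoral"
  reference_region(unlist(box$min), unlist(box$max), frame_tag = tag)
}

frame_for_tag <- function(tag, frames) {
  switch(tag, world = NULL, femoral = frames$femoral, tibial = frames$tibial)
}

#' Run the full SPECT/CT analysis pipeline
#'
#' Reads the CT/SPECT pair and landmarks, constructs the femoral (and, when
#' a talus landmark is present, tibial) frames, computes reference-region
#' statistics and the normalisation model, derives the raw threshold,
#' segments the hotspot inside the ROI, computes hotspot metrics and the
#' global/saved/local histogram triplet, and (optionally) extracts bone and
#' hotspot meshes. All artifacts are written under `config$out_dir`:
#' `frames.json`, `reference_stats.json`, `histogram_triplet.csv`,
#' `hotspot_metrics.json` / `.csv`, `hotspot_mask.nii.gz`, mesh PLYs, and
#' `run_log.json` (config hash, package/R versions).
#'
#' @param config An [analysis_config()] (or a path to a config file).
#' @return Invisibly, a list with `frames`, `ref_stats`, `model`,
#'   `threshold_raw`, `mask`, `metrics`, `histograms`, `realignment`,
#'   and the output paths.
#' @export
run_analyze <- function(config) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  ct <- load_volume_input(config$ct, "CT")
  spect <- load_volume_input(config$spect, "SPECT")
  lm <- read_landmarks(config$landmarks)

  fem <- femoral_frame(lm)
  frames <- list(femoral = fem)
  if (!is.null(lm$talus_centre)) {
    kc <- knee_centre(lm$medial_epicondyle, lm$lateral_epicondyle)
    frames$tibial <- tibial_frame(fem, kc, lm$talus_centre)
  }
  realign <- frame_rotation(NULL, fem)

  ref_region <- region_from_cfg(config$reference_region)
  ref_stats <- region_stats(spect, ref_region,
                            frame_for_tag(ref_region$frame_tag, frames))
  model <- normalization_model(ref_stats, config$normalization)

  threshold_raw <- if (!is.null(config$threshold$max_fraction)) {
    max_fraction_threshold(spect, config$threshold$max_fraction)
  } else {
    threshold_from_model(model, config$threshold)
  }

  roi <- region_from_cfg(config$roi)
  roi_frame <- frame_for_tag(roi$frame_tag, frames)
  mask <- hotspot_mask(spect, roi, threshold_raw, roi_frame)
  metrics <- hotspot_metrics(spect, mask, model, frame = fem,
                             ref = ref_stats, threshold_raw = threshold_raw)
  hist3 <- histogram_triplet(spect, ref_region, roi,
                             frame = frame_for_tag(
                               if (ref_region$frame_tag != "world")
                                 ref_region$frame_tag else roi$frame_tag,
                               frames))

  out <- function(f) file.path(config$out_dir, f)
  write_frame(fem, out("femoral_frame.json"))
  if (!is.null(frames$tibial)) {
    write_frame(frames$tibial, out("tibial_frame.json"))
  }
  jsonlite::write_json(
    list(reference = unclass(ref_stats)[c("n", "mean", "sd", "min", "max")],
         normalization = config$normalization,
         threshold_raw = threshold_raw,
         realignment = realign),
    out("reference_stats.json"), auto_unbox = TRUE, digits = NA)
  hist_df <- data.frame(
    bin_low = hist3$breaks[-length(hist3$breaks)],
    bin_high = hist3$breaks[-1],
    global = hist3$global$counts,
    saved = hist3$saved$counts,
    local = hist3$local$counts
  )
  utils::write.csv(hist_df, out("histogram_triplet.csv"), row.names = FALSE)
  metrics_list <- unclass(metrics)
  jsonlite::write_json(metrics_list, out("hotspot_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(metric = names(metrics_list),
               value = vapply(metrics_list, function(x)
                 paste(format(x, digits = 15), collapse = ";"),
                 character(1))),
    out("hotspot_metrics.csv"), row.names = FALSE)
  write_mask(mask, out("hotspot_mask.nii.gz"))

  meshes <- NULL
  if (isTRUE(config$mesh$enabled)) {
    bone_level <- config$mesh$bone_level %||% 150
    bone_mesh <- extract_isosurface(ct, bone_level, frame = fem,
                                    label = "bone")
    hot_mesh <- extract_isosurface(spect, threshold_raw, frame = fem,
                                   label = "hotspot")
    scene_export(bone_mesh, hot_mesh, out("scene"))
    meshes <- list(bone = bone_mesh, hotspot = hot_mesh)
  }

  cfg_json <- out("config_used.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(
    list(config_hash = unname(tools::md5sum(cfg_json)),
         package_version = as.character(utils::packageVersion("orthospect")),
         r_version = R.version.string,
         seed = config$seed),
    out("run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(frames = frames, ref_stats = ref_stats, model = model,
                 threshold_raw = threshold_raw, mask = mask,
                 metrics = metrics, histograms = hist3,
                 realignment = realign, meshes = meshes,
                 out_dir = config$out_dir))
}

#' Compare two analyses side by side
#'
#' Runs (or reuses) two analyses and tabulates their normalised metrics —
#' uptake ratios, voxel counts and volumes — with differences and ratios.
#' Comparisons are only meaningful under identical threshold rules and
#' normalisation modes, so differing rules are an error.
#'
#' @param config_a,config_b [analysis_config()] objects (or paths).
#' @param out_csv Optional path for the comparison table.
#' @return A data.frame with columns `metric`, `a`, `b`, `difference`,
#'   `ratio`.
#' @export
run_compare <- function(config_a, config_b, out_csv = NULL) {
  if (is.character(config_a)) config_a <- read_config(config_a)
  if (is.character(config_b)) config_b <- read_config(config_b)
  if (!identical(config_a$threshold, config_b$threshold) ||
      !identical(config_a$normalization, config_b$normalization)) {
    stop("comparison requires identical threshold rules and ",
         "normalization modes")
  }
  res_a <- run_analyze(config_a)
  res_b <- run_analyze(config_b)
  ma <- res_a$metrics
  mb <- res_b$metrics
  rows <- c("max_ratio", "mean_ratio", "voxel_count", "volume_mm3",
            "volume_ml", "t")
  tab <- data.frame(
    metric = rows,
    a = vapply(rows, function(r) as.numeric(ma[[r]]), numeric(1)),
    b = vapply(rows, function(r) as.numeric(mb[[r]]), numeric(1))
  )
  tab$difference <- tab$b - tab$a
  tab$ratio <- ifelse(tab$a != 0, tab$b / tab$a, NA_real_)
  rownames(tab) <- NULL
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
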