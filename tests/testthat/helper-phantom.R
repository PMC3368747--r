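# Reduced-size phantom used where tests exercise the full pipeline: the
# same construction as the defaults, but a shorter limb and coarser grids
# so a pipeline run takes a fraction of a second. The reference region is
# shifted to stay mid-shaft for the shorter femur.

small_phantom_spec <- function(hotspots = list(list(centre = c(0, 30, 10),
                                                    semi_axes = c(11, 9, 11),
                                                    ratio = 4)), ...) {
  phantom_spec(shaft_length = 200, tibia_length = 170, soft_radius = 45,
               ct_spacing = 3, spect_spacing = 3, hotspots = hotspots, ...)
}

small_ref_region <- function() {
  reference_region(c(-20, -20, 100), c(20, 20, 150), frame_tag = "femoral")
}

small_roi <- function() {
  reference_region(c(-45, -45, -35), c(45, 45, 50), frame_tag = "femoral")
}

# write a phantom to disk as the pipeline inputs (volumes + landmarks)
write_phantom_inputs <- function(ph, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(ph$ct, file.path(dir, "ct.nii.gz"))
  write_volume(ph$spect, file.path(dir, "spect.nii.gz"))
  write_landmarks(ph$truth$landmarks, file.path(dir, "landmarks.json"))
  list(ct = file.path(dir, "ct.nii.gz"),
       spect = file.path(dir, "spect.nii.gz"),
       landmarks = file.path(dir, "landmarks.json"))
}

small_config <- function(paths, out_dir, ...) {
  analysis_config(
    ct = paths$ct, spect = paths$spect, landmarks = paths$landmarks,
    out_dir = out_dir,
    reference_region = list(min = c(-20, -20, 100), max = c(20, 20, 150),
                            frame = "femoral"),
    roi = list(min = c(-45, -45, -35), max = c(45, 45, 50),
               frame = "femoral"),
    mesh = list(enabled = FALSE),
    ...
  )
}
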