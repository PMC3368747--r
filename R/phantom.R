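# Synthetic co-registered CT/SPECT knee phantoms with ground truth.
# Geometry is built in an "unposed scene" coordinate system: knee centre at
# the origin, femoral mechanical axis along +z (head centre at
# (0,0,shaft_length)), transepicondylar line along x, tibia along -z. A
# rigid pose (rotation + translation) then places the whole scene in world
# (scanner) coordinates, emulating arbitrary patient position. Hotspot
# centres are specified in anatomical (ML, AP, PROX) coordinates so they
# mean the same thing for either limb side.

#' Specification of a synthetic knee phantom
#'
#' Defines the bone geometry (femoral shaft cylinder + spherical head, two
#' condylar spheres carrying the epicondyle landmarks, tibial cylinder +
#' talus sphere, all inside a soft-tissue envelope), the SPECT uptake model
#' (uniform background level `background` in tissue, `background * ratio`
#' inside each ellipsoidal hotspot, zero in air), Poisson counting noise,
#' the rigid patient pose, and the CT/SPECT grid spacings (the two grids
#' may differ; world coordinates are their only common frame).
#'
#' @param shaft_length Knee centre to femoral head centre, mm.
#' @param shaft_radius,head_radius,condyle_radius,condyle_offset Femoral
#'   geometry, mm; epicondyle landmarks sit at
#'   `x = +/-(condyle_offset + condyle_radius)`.
#' @param tibia_length Knee centre to talus centre, mm.
#' @param tibia_radius,talus_radius Tibial geometry, mm.
#' @param soft_radius Soft-tissue envelope radius, mm.
#' @param background SPECT background uptake in tissue, counts (> 0).
#' @param hotspots List of hotspots, each
#'   `list(centre = c(ML, AP, PROX) mm, semi_axes = c(a, b, c) mm,
#'   ratio = r >= 1)`.
#' @param pose `list(rotation = 3x3, translation = length-3)`, the rigid
#'   map from scene to world coordinates.
#' @param ct_spacing,spect_spacing Grid spacings, mm (scalar or length 3).
#' @param noise `"none"` or `"poisson"` (SPECT counting noise).
#' @param ct_noise_sd Optional Gaussian CT noise sd (HU), default 0 (off).
#' @param side Limb side; for `"left"` the unposed anatomical frame
#'   coincides with the scanner axes.
#' @param seed Integer seed; the same spec is bit-reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shaft_length = 350, shaft_radius = 15,
                         head_radius = 23, condyle_radius = 20,
                         condyle_offset = 20,
                         tibia_length = 320, tibia_radius = 14,
                         talus_radius = 16, soft_radius = 55,
                         background = 100,
                         hotspots = list(list(centre = c(0, 35, 15),
                                              semi_axes = c(12, 10, 12),
                                              ratio = 4)),
                         pose = list(rotation = diag(3),
                                     translation = c(0, 0, 0)),
                         ct_spacing = 2, spect_spacing = 3,
                         noise = c("none", "poisson"),
                         ct_noise_sd = 0,
                         side = c("left", "right"), seed = 1L) {
  noise <- match.arg(noise)
  side <- match.arg(side)
  lens <- c(shaft_length, shaft_radius, head_radius, condyle_radius,
            condyle_offset, tibia_length, tibia_radius, talus_radius,
            soft_radius)
  if (any(lens <= 0)) stop("all phantom lengths must be positive")
  if (background <= 0) stop("background uptake must be positive")
  for (h in hotspots) {
    if (length(h$centre) != 3L || length(h$semi_axes) != 3L ||
        any(h$semi_axes <= 0)) {
      stop("each hotspot needs a 3-vector centre and positive semi-axes")
    }
    if (h$ratio < 1) stop("hotspot ratio must be >= 1")
  }
  if (!is_rotation(pose$rotation)) {
    stop("pose$rotation must be a proper rotation matrix")
  }
  structure(
    list(shaft_length = shaft_length, shaft_radius = shaft_radius,
         head_radius = head_radius, condyle_radius = condyle_radius,
         condyle_offset = condyle_offset, tibia_length = tibia_length,
         tibia_radius = tibia_radius, talus_radius = talus_radius,
         soft_radius = soft_radius, background = background,
         hotspots = hotspots, pose = pose,
         ct_spacing = rep(as.numeric(ct_spacing), length.out = 3L),
         spect_spacing = rep(as.numeric(spect_spacing), length.out = 3L),
         noise = noise, ct_noise_sd = ct_noise_sd, side = side,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# anatomical (ML, AP, PROX) axes of the unposed scene, per limb side:
# rows of the returned matrix are the axis directions in scene coordinates
scene_anatomic_axes <- function(side) {
  if (side == "left") {
    rbind(ML = c(1, 0, 0), AP = c(0, 1, 0), PROX = c(0, 0, 1))
  } else {
    rbind(ML = c(-1, 0, 0), AP = c(0, -1, 0), PROX = c(0, 0, 1))
  }
}

#' Generate a synthetic CT/SPECT phantom pair with ground truth
#'
#' Builds the CT volume (bone ~ +700 HU, soft tissue 0, air -1024), the
#' SPECT volume (background counts in tissue, elevated counts in hotspot
#' ellipsoids, optional Poisson noise) and the ground truth: posed
#' landmarks, posed femoral/tibial frames, each hotspot's true ellipsoid
#' volume and intensity ratio, and the true background level.
#'
#' @param spec A [phantom_spec()].
#' @return List with `ct`, `spect` ([image_volume()]s) and `truth` (list
#'   with `landmarks`, `femoral_frame`, `tibial_frame`, `hotspots`,
#'   `background`).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  axes0 <- scene_anatomic_axes(spec$side)
  # hotspot geometry in scene coordinates
  hs_scene <- lapply(spec$hotspots, function(h) {
    list(centre = as.numeric(t(axes0) %*% h$centre),
         semi_axes = abs(as.numeric(t(axes0) %*% h$semi_axes)),
         ratio = h$ratio)
  })
  zmin <- -(spec$tibia_length + spec$talus_radius + 5)
  zmax <- spec$shaft_length + spec$head_radius + 5
  for (h in hs_scene) {
    if (max(abs(h$centre[1:2]) + h$semi_axes[1:2]) > spec$soft_radius ||
        h$centre[3] - h$semi_axes[3] < zmin ||
        h$centre[3] + h$semi_axes[3] > zmax) {
      stop("hotspot extends outside the soft-tissue envelope")
    }
  }
  R <- spec$pose$rotation
  tr <- as.numeric(spec$pose$translation)
  # world bounding box of the posed scene
  ext <- spec$soft_radius + 8
  corners <- as.matrix(expand.grid(x = c(-ext, ext), y = c(-ext, ext),
                                   z = c(zmin - 8, zmax + 8)))
  wc <- t(R %*% t(corners) + tr)
  lo <- apply(wc, 2, min)
  hi <- apply(wc, 2, max)

  grid_volume <- function(spacing, modality, field_fun) {
    n <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)))
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing)
    affine[1:3, 4] <- lo + spacing / 2
    i <- rep.int(seq_len(n[1]) - 1, n[2] * n[3])
    j <- rep.int(rep(seq_len(n[2]) - 1, each = n[1]), n[3])
    k <- rep(seq_len(n[3]) - 1, each = n[1] * n[2])
    w <- cbind(lo[1] + (i + 0.5) * spacing[1],
               lo[2] + (j + 0.5) * spacing[2],
               lo[3] + (k + 0.5) * spacing[3])
    s <- t(t(R) %*% (t(w) - tr))       # world -> scene
    vals <- field_fun(s)
    image_volume(array(vals, dim = n), affine, modality)
  }

  in_tissue <- function(s) {
    s[, 1]^2 + s[, 2]^2 <= spec$soft_radius^2 &
      s[, 3] >= zmin & s[, 3] <= zmax
  }
  in_bone <- function(s) {
    r2 <- s[, 1]^2 + s[, 2]^2
    shaft <- r2 <= spec$shaft_radius^2 &
      s[, 3] >= 25 & s[, 3] <= spec$shaft_length
    head <- r2 + (s[, 3] - spec$shaft_length)^2 <= spec$head_radius^2
    cond <- ((s[, 1] - spec$condyle_offset)^2 + s[, 2]^2 + s[, 3]^2 <=
               spec$condyle_radius^2) |
            ((s[, 1] + spec$condyle_offset)^2 + s[, 2]^2 + s[, 3]^2 <=
               spec$condyle_radius^2)
    tib <- r2 <= spec$tibia_radius^2 &
      s[, 3] <= -25 & s[, 3] >= -spec$tibia_length
    tal <- r2 + (s[, 3] + spec$tibia_length)^2 <= spec$talus_radius^2
    shaft | head | cond | tib | tal
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(spec$seed)

  ct <- grid_volume(spec$ct_spacing, "CT", function(s) {
    v <- rep(-1024, nrow(s))
    tis <- in_tissue(s)
    v[tis] <- 0
    v[tis & in_bone(s)] <- 700
    if (spec$ct_noise_sd > 0) {
      v <- v + stats::rnorm(length(v), 0, spec$ct_noise_sd)
    }
    v
  })
  spect <- grid_volume(spec$spect_spacing, "SPECT", function(s) {
    v <- rep(0, nrow(s))
    tis <- in_tissue(s)
    v[tis] <- spec$background
    for (h in hs_scene) {
      u <- sweep(s, 2, h$centre)
      inside <- (u[, 1] / h$semi_axes[1])^2 + (u[, 2] / h$semi_axes[2])^2 +
        (u[, 3] / h$semi_axes[3])^2 <= 1
      v[inside & tis] <- spec$background * h$ratio
    }
    if (spec$noise == "poisson") v <- stats::rpois(length(v), v)
    as.numeric(v)
  })

  # posed landmarks and ground-truth frames
  pose_pt <- function(p) as.numeric(R %*% p + tr)
  epi_x <- spec$condyle_offset + spec$condyle_radius
  med_scene <- if (spec$side == "left") c(-epi_x, 0, 0) else c(epi_x, 0, 0)
  lat_scene <- -med_scene
  lm <- landmark_set(
    medial_epicondyle = pose_pt(med_scene),
    lateral_epicondyle = pose_pt(lat_scene),
    femoral_head_centre = pose_pt(c(0, 0, spec$shaft_length)),
    talus_centre = pose_pt(c(0, 0, -spec$tibia_length)),
    side = spec$side
  )
  axes_world <- axes0 %*% t(R)   # rows: posed anatomical axes
  fem <- anatomic_frame(tr, axes_world, bone = "femur")
  tib <- anatomic_frame(tr, axes_world, bone = "tibia")
  truth <- list(
    landmarks = lm,
    femoral_frame = fem,
    tibial_frame = tib,
    hotspots = lapply(spec$hotspots, function(h) {
      list(centre_anatomic = h$centre,
           volume_mm3 = 4 / 3 * pi * prod(h$semi_axes),
           ratio = h$ratio)
    }),
    background = spec$background
  )
  list(ct = ct, spect = spect, truth = truth)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Two-patient exemplar scenario
#'
#' A pair of phantoms echoing a typical two-patient comparison of
#' symptomatic patellofemoral joints: "P1" has a single isolated
#' patellofemoral hotspot (uptake ratio 4.5) scanned in neutral pose;
#' "P2" has a larger patellofemoral hotspot (ratio 5.5) with a secondary
#' lobe extending towards the tibiofemoral compartment, and lies in the
#' scanner rotated 8 degrees axially (plus a small translation), so its
#' anatomical realignment exceeds 5 degrees. Parameters echo, not
#' reproduce, clinical data.
#'
#' @param seed Integer seed for the Poisson counting noise.
#' @param noise `"poisson"` (default) or `"none"` for exact arithmetic.
#' @param spect_spacing SPECT grid spacing, mm.
#' @return List with elements `p1` and `p2`, each a [make_phantom()]
#'   result plus its `spec`.
#' @export
two_patient_scenario <- function(seed = 1L, noise = c("poisson", "none"),
                                 spect_spacing = 3) {
  noise <- match.arg(noise)
  p1_spec <- phantom_spec(
    hotspots = list(list(centre = c(0, 35, 15), semi_axes = c(12, 10, 12),
                         ratio = 4.5)),
    noise = noise, side = "left", seed = seed,
    spect_spacing = spect_spacing
  )
  p2_spec <- phantom_spec(
    hotspots = list(
      list(centre = c(0, 35, 15), semi_axes = c(16, 13, 16), ratio = 5.5),
      list(centre = c(8, 30, -22), semi_axes = c(10, 8, 10), ratio = 5.5)
    ),
    pose = list(rotation = rotation_about(c(0, 0, 1), 8),
                translation = c(6, -4, 10)),
    noise = noise, side = "left", seed = seed + 1L,
    spect_spacing = spect_spacing
  )
  list(p1 = c(make_phantom(p1_spec), list(spec = p1_spec)),
       p2 = c(make_phantom(p2_spec), list(spec = p2_spec)))
}
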