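#' Anatomical landmark set for the lower limb
#'
#' Named anatomical points in world (LPS) millimetres used to construct the
#' femoral and tibial reference frames: the femoral head centre (given
#' directly or fitted from head-surface points via [fit_head_centre()]),
#' the medial and lateral epicondyles, and optionally the talus centre
#' (required for the tibial frame).
#'
#' @param medial_epicondyle,lateral_epicondyle Length-3 points, world mm.
#' @param femoral_head_centre Optional length-3 point; if `NULL`,
#'   `head_surface_points` must be supplied and the centre is fitted.
#' @param head_surface_points Optional matrix (>= 4 non-coplanar rows) of
#'   points on the femoral head surface.
#' @param talus_centre Optional length-3 point (tibial frame endpoint).
#' @param side `"left"` or `"right"` limb.
#' @return An object of class `landmark_set`. If the head centre was fitted,
#'   the fit radius is stored as attribute `head_fit_radius`.
#' @export
landmark_set <- function(medial_epicondyle, lateral_epicondyle,
                         femoral_head_centre = NULL,
                         head_surface_points = NULL,
                         talus_centre = NULL,
                         side = c("left", "right")) {
  side <- match.arg(side)
  med <- as.numeric(medial_epicondyle)
  lat <- as.numeric(lateral_epicondyle)
  stopifnot(length(med) == 3L, length(lat) == 3L)
  if (vnorm(lat - med) <= 1) {
    stop("epicondyles must be distinct (separation > 1 mm)")
  }
  fit_radius <- NULL
  if (is.null(femoral_head_centre)) {
    if (is.null(head_surface_points)) {
      stop("either femoral_head_centre or head_surface_points is required")
    }
    fit <- fit_head_centre(head_surface_points)
    femoral_head_centre <- fit$centre
    fit_radius <- fit$radius
  }
  head <- as.numeric(femoral_head_centre)
  stopifnot(length(head) == 3L)
  kc <- knee_centre(med, lat)
  if (vnorm(head - kc) <= 1) {
    stop("femoral head centre must be > 1 mm from the knee centre")
  }
  if (!is.null(talus_centre)) {
    talus_centre <- as.numeric(talus_centre)
    stopifnot(length(talus_centre) == 3L)
  }
  out <- structure(
    list(femoral_head_centre = head, medial_epicondyle = med,
         lateral_epicondyle = lat, talus_centre = talus_centre, side = side),
    class = "landmark_set"
  )
  attr(out, "head_fit_radius") <- fit_radius
  out
}

#' Knee centre from the epicondyles
#'
#' The midpoint of the straight line joining the surface locations of the
#' medial and lateral epicondyles.
#'
#' @param medial_epi,lateral_epi Length-3 points in world mm.
#' @return A length-3 point.
#' @export
knee_centre <- function(medial_epi, lateral_epi) {
  medial_epi <- as.numeric(medial_epi)
  lateral_epi <- as.numeric(lateral_epi)
  if (vnorm(lateral_epi - medial_epi) <= 1) {
    stop("epicondyles must be distinct (separation > 1 mm)")
  }
  (medial_epi + lateral_epi) / 2
}

#' Least-squares sphere fit for the femoral head centre
#'
#' Operationalises "the intersection of the diameters of the head in all
#' three planes" as a sphere fit: an algebraic linear least-squares
#' initialisation followed by Gauss-Newton refinement of the geometric
#' (orthogonal-distance) residuals.
#'
#' @param head_surface_points Matrix (n x 3, n >= 4) of non-coplanar points
#'   on the head surface, world mm.
#' @return A list with `centre` (length-3), `radius`, and `rms` residual.
#' @export
fit_head_centre <- function(head_surface_points) {
  P <- rbind_pts(head_surface_points)
  if (nrow(P) < 4L) stop("at least 4 head surface points are required")
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))$d
  if (sv[3] < max(sv[1] * 1e-8, 1e-9)) {
    stop("head surface points are (near-)coplanar; sphere fit is degenerate")
  }
  # algebraic fit: |p|^2 = 2 c . p + (r^2 - |c|^2), linear in (c, d)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  beta <- qr.solve(A, b)
  centre <- beta[1:3]
  radius <- sqrt(max(beta[4] + sum(centre^2), 0))
  # Gauss-Newton on residuals r_i = |p_i - c| - r
  for (iter in 1:10) {
    diffs <- sweep(P, 2, centre, "-")
    dist <- sqrt(rowSums(diffs^2))
    if (any(dist < 1e-12)) break
    res <- dist - radius
    J <- cbind(-diffs / dist, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    centre <- centre + step[1:3]
    radius <- radius + step[4]
    if (max(abs(step)) < 1e-10) break
  }
  diffs <- sweep(P, 2, centre, "-")
  res <- sqrt(rowSums(diffs^2)) - radius
  list(centre = as.numeric(centre), radius = radius,
       rms = sqrt(mean(res^2)))
}

#' Anatomical reference frame
#'
#' An origin (the knee centre) plus an orthonormal right-handed axis triad
#' expressed in world coordinates. Axis rows are, in order, ML
#' (mediolateral, medial to lateral), AP (anteroposterior) and PROX
#' (the mechanical axis, distal to proximal).
#'
#' @param origin Length-3 world point (mm).
#' @param axes 3x3 matrix with unit rows ML, AP, PROX.
#' @param bone `"femur"`, `"tibia"` or `"world"`.
#' @return An object of class `anatomic_frame`.
#' @export
anatomic_frame <- function(origin, axes, bone = c("femur", "tibia", "world")) {
  bone <- match.arg(bone)
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, is.matrix(axes), all(dim(axes) == c(3, 3)))
  check_orthonormal(axes)
  rownames(axes) <- c("ML", "AP", "PROX")
  structure(list(origin = origin, axes = axes, bone = bone),
            class = "anatomic_frame")
}

check_orthonormal <- function(axes, tol = 1e-6) {
  if (max(abs(axes %*% t(axes) - diag(3))) > tol) {
    stop("frame axes must be orthonormal unit vectors")
  }
  if (det(axes) < 0) stop("frame axes must be right-handed (det +1)")
  invisible(TRUE)
}

#' Scanner-aligned identity frame
#'
#' The trivial frame whose axes coincide with the world (scanner) axes;
#' used as the "before realignment" reference when quantifying how far a
#' patient's anatomy sits from the scanner axes.
#'
#' @param origin Frame origin, default the world origin.
#' @return An `anatomic_frame` with identity axes.
#' @export
identity_frame <- function(origin = c(0, 0, 0)) {
  anatomic_frame(origin, diag(3), bone = "world")
}

#' @export
print.anatomic_frame <- function(x, ...) {
  cat(sprintf("<anatomic_frame %s, origin (%s) mm>\n", x$bone,
              paste(signif(x$origin, 6), collapse = ", ")))
  print(signif(x$axes, 6))
  invisible(x)
}

#' Femoral anatomical reference frame from landmarks
#'
#' The mechanical axis runs from the knee centre (midpoint of the
#' transepicondylar line) to the femoral head centre. The AP axis is the
#' cross product of the transepicondylar line and the mechanical axis, and
#' the ML axis the cross product of AP and the mechanical axis; AP and ML
#' are then jointly flipped if needed so that ML points medial to lateral,
#' keeping the triad right-handed. Origin is the knee centre.
#'
#' @param landmarks A [landmark_set()].
#' @return An `anatomic_frame` with `bone = "femur"`.
#' @export
femoral_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "landmark_set"))
  kc <- knee_centre(landmarks$medial_epicondyle, landmarks$lateral_epicondyle)
  prox_raw <- landmarks$femoral_head_centre - kc
  if (vnorm(prox_raw) <= 1) {
    stop("femoral head centre must be > 1 mm from the knee centre")
  }
  PROX <- unitv(prox_raw)
  tep <- unitv(landmarks$lateral_epicondyle - landmarks$medial_epicondyle)
  # degenerate when mechanical axis nearly parallel to transepicondylar line
  if (vnorm(cross3(tep, PROX)) < sin(1 * pi / 180)) {
    stop("mechanical axis is (near-)parallel to the transepicondylar line")
  }
  AP <- unitv(cross3(tep, PROX))
  ML <- unitv(cross3(AP, PROX))
  if (sum(ML * tep) < 0) {
    AP <- -AP
    ML <- -ML
  }
  anatomic_frame(kc, rbind(ML, AP, PROX), bone = "femur")
}

#' Tibial anatomical reference frame (hinge-knee construction)
#'
#' Treats the knee as a simple hinge: the tibial ML axis is the femoral ML
#' axis; the tibial long axis runs from the talus centre distally to the
#' knee centre proximally; AP is the cross product of the long axis and ML,
#' and PROX the cross product of ML and AP, signed so PROX points distal to
#' proximal. Origin is the knee centre.
#'
#' @param femoral An `anatomic_frame` for the femur.
#' @param knee_centre Length-3 world point (mm).
#' @param talus_centre Length-3 world point (mm).
#' @return An `anatomic_frame` with `bone = "tibia"`.
#' @export
tibial_frame <- function(femoral, knee_centre, talus_centre) {
  stopifnot(inherits(femoral, "anatomic_frame"))
  knee_centre <- as.numeric(knee_centre)
  talus_centre <- as.numeric(talus_centre)
  long_raw <- knee_centre - talus_centre
  if (vnorm(long_raw) <= 1) {
    stop("talus centre must be > 1 mm from the knee centre")
  }
  L <- unitv(long_raw)
  ML <- femoral$axes["ML", ]
  if (vnorm(cross3(L, ML)) < sin(1 * pi / 180)) {
    stop("tibial long axis is (near-)parallel to the femoral ML axis")
  }
  AP <- unitv(cross3(L, ML))
  PROX <- unitv(cross3(ML, AP))
  if (sum(PROX * L) < 0) {
    AP <- -AP
    PROX <- -PROX
  }
  anatomic_frame(knee_centre, rbind(ML, AP, PROX), bone = "tibia")
}

#' Rotation between two anatomical frames
#'
#' Quantifies realignment: the total rotation angle between the axis triads
#' of two frames, plus the signed axial component (rotation about the first
#' frame's PROX axis, the mechanical axis).
#'
#' @param a First frame, or `NULL` for the scanner identity frame.
#' @param b Second frame.
#' @return List with `total_deg` (rotation angle, degrees, in \[0, 180\])
#'   and `about_PROX_deg` (signed axial rotation, degrees, in (-180, 180\]).
#' @export
frame_rotation <- function(a, b) {
  if (is.null(a)) a <- identity_frame()
  stopifnot(inherits(a, "anatomic_frame"), inherits(b, "anatomic_frame"))
  # R maps frame-a axes onto frame-b axes (world vectors): R a_i = b_i
  R <- t(b$axes) %*% a$axes
  total <- acos(clamp1((sum(diag(R)) - 1) / 2)) * 180 / pi
  p <- a$axes["PROX", ]
  u <- a$axes["ML", ]              # transverse axis, perpendicular to PROX
  v <- as.numeric(R %*% u)
  v_t <- v - sum(v * p) * p        # project image into the transverse plane
  about <- atan2(sum(cross3(u, v_t) * p), sum(u * v_t)) * 180 / pi
  list(total_deg = total, about_PROX_deg = about)
}

#' Map points between world and anatomic coordinates
#'
#' Anatomic coordinates express a point relative to the frame origin along
#' the (ML, AP, PROX) axes; `anatomic_to_world()` is the exact inverse.
#'
#' @param p Length-3 point or n x 3 matrix.
#' @param frame An `anatomic_frame`.
#' @return Point(s) with the same shape as `p`.
#' @export
world_to_anatomic <- function(p, frame) {
  stopifnot(inherits(frame, "anatomic_frame"))
  vec <- is.null(dim(p))
  p <- rbind_pts(p)
  out <- sweep(p, 2, frame$origin, "-") %*% t(frame$axes)
  if (vec && nrow(out) == 1L) as.numeric(out) else out
}

#' @rdname world_to_anatomic
#' @export
anatomic_to_world <- function(p, frame) {
  stopifnot(inherits(frame, "anatomic_frame"))
  vec <- is.null(dim(p))
  p <- rbind_pts(p)
  out <- sweep(p %*% frame$axes, 2, frame$origin, "+")
  if (vec && nrow(out) == 1L) as.numeric(out) else out
}

#' Read / write landmark files
#'
#' Landmark files are JSON with keys matching the [landmark_set()] fields
#' (`medial_epicondyle`, `lateral_epicondyle`, `femoral_head_centre` or
#' `head_surface_points`, optional `talus_centre`, required `side`),
#' coordinates in world (LPS) mm.
#'
#' @param path File path.
#' @return `read_landmarks()` returns a `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmarks file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$side)) stop("landmarks file must declare 'side'")
  hsp <- x$head_surface_points
  if (!is.null(hsp)) hsp <- rbind_pts(as.matrix(hsp))
  landmark_set(
    medial_epicondyle = x$medial_epicondyle,
    lateral_epicondyle = x$lateral_epicondyle,
    femoral_head_centre = x$femoral_head_centre,
    head_surface_points = hsp,
    talus_centre = x$talus_centre,
    side = x$side
  )
}

#' @rdname read_landmarks
#' @param landmarks A `landmark_set` to serialise.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  x <- landmarks[!vapply(landmarks, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialise / load an anatomic frame as JSON
#'
#' @param frame An `anatomic_frame`.
#' @param path File path.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "anatomic_frame"))
  jsonlite::write_json(
    list(origin = frame$origin,
         axes = apply(frame$axes, 1, identity, simplify = FALSE),
         bone = frame$bone),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  axes <- rbind(x$axes$ML, x$axes$AP, x$axes$PROX)
  anatomic_frame(x$origin, axes, bone = x$bone)
}
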