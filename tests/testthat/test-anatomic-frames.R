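test_that("knee centre is the transepicondylar midpoint", {
  expect_equal(knee_centre(c(-40, 0, 0), c(40, 0, 0)), c(0, 0, 0))
  expect_equal(knee_centre(c(10, 20, 30), c(30, 40, 50)), c(20, 30, 40))
  expect_error(knee_centre(c(0, 0, 0), c(0, 0, 0)), "distinct")
})

test_that("sphere fit recovers an exact femoral head centre", {
  centre <- c(1, 2, 3)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  pts <- sweep(dirs * 25, 2, centre, "+")
  fit <- fit_head_centre(pts)
  expect_lt(max(abs(fit$centre - centre)), 1e-6)
  expect_lt(abs(fit$radius - 25), 1e-6)
})

test_that("sphere fit is accurate under measurement noise", {
  set.seed(42)
  centre <- c(1, 2, 3)
  u <- matrix(rnorm(200 * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 25, 2, centre, "+") + matrix(rnorm(600, 0, 0.5), ncol = 3)
  fit <- fit_head_centre(pts)
  expect_lt(sqrt(sum((fit$centre - centre)^2)), 0.2)
})

test_that("sphere fit rejects coplanar points", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(2, 3, 0))
  expect_error(fit_head_centre(pts), "coplanar")
  expect_error(fit_head_centre(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "at least 4")
})

test_that("femoral frame matches the closed form on axis-aligned landmarks", {
  lm <- landmark_set(medial_epicondyle = c(-40, 0, 0),
                     lateral_epicondyle = c(40, 0, 0),
                     femoral_head_centre = c(0, 0, 400), side = "left")
  f <- femoral_frame(lm)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(unname(f$axes["PROX", ]), c(0, 0, 1))
  expect_equal(unname(f$axes["ML", ]), c(1, 0, 0))
  expect_equal(unname(f$axes["AP", ]), c(0, 1, 0))
  # ML points medial -> lateral regardless of which epicondyle is medial
  lm_r <- landmark_set(medial_epicondyle = c(40, 0, 0),
                       lateral_epicondyle = c(-40, 0, 0),
                       femoral_head_centre = c(0, 0, 400), side = "right")
  f_r <- femoral_frame(lm_r)
  expect_equal(unname(f_r$axes["ML", ]), c(-1, 0, 0))
  expect_gt(det(f_r$axes), 0)
})

test_that("femoral frame rejects a head collinear with the epicondylar line", {
  lm <- landmark_set(medial_epicondyle = c(-40, 0, 0),
                     lateral_epicondyle = c(40, 0, 0),
                     femoral_head_centre = c(400, 0, 0), side = "left")
  expect_error(femoral_frame(lm), "parallel")
})

test_that("tibial frame treats the knee as a hinge", {
  lm <- landmark_set(medial_epicondyle = c(-40, 0, 0),
                     lateral_epicondyle = c(40, 0, 0),
                     femoral_head_centre = c(0, 0, 400), side = "left")
  fem <- femoral_frame(lm)
  # aligned limb: tibial frame equals femoral frame
  tib <- tibial_frame(fem, c(0, 0, 0), c(0, 0, -380))
  expect_lt(max(abs(tib$axes - fem$axes)), 1e-12)
  # displaced talus tilts PROX in the y-z plane; triad stays orthonormal
  tib2 <- tibial_frame(fem, c(0, 0, 0), c(0, 50, -380))
  L <- c(0, -50, 380) / sqrt(50^2 + 380^2)
  expect_equal(unname(tib2$axes["ML", ]), c(1, 0, 0))
  expect_lt(max(abs(tib2$axes["PROX", ] - L)), 1e-12)
  expect_lt(abs(sum(tib2$axes["ML", ] * tib2$axes["AP", ])), 1e-9)
  expect_error(tibial_frame(fem, c(0, 0, 0), c(0, 0, 0)), "1 mm")
})

test_that("constructed frames are orthonormal, right-handed and pose-equivariant", {
  set.seed(7)
  for (rep in 1:50) {
    lm <- random_landmarks()
    fem <- femoral_frame(lm)
    kc <- knee_centre(lm$medial_epicondyle, lm$lateral_epicondyle)
    tib <- tibial_frame(fem, kc, lm$talus_centre)
    for (f in list(fem, tib)) {
      expect_lt(max(abs(f$axes %*% t(f$axes) - diag(3))), 1e-9)
      expect_lt(abs(det(f$axes) - 1), 1e-9)
    }
    R <- random_rotation()
    t <- runif(3, -100, 100)
    fem2 <- femoral_frame(transform_landmarks(lm, R, t))
    expect_lt(max(abs(fem2$axes - fem$axes %*% t(R))), 1e-9)
    expect_lt(max(abs(fem2$origin - (R %*% fem$origin + t))), 1e-9)
  }
})

test_that("frame_rotation recovers injected rotations exactly", {
  lm <- landmark_set(medial_epicondyle = c(-40, 0, 0),
                     lateral_epicondyle = c(40, 0, 0),
                     femoral_head_centre = c(0, 0, 400), side = "left")
  a <- femoral_frame(lm)
  expect_equal(frame_rotation(a, a), list(total_deg = 0, about_PROX_deg = 0))
  for (theta in c(1, 5, 30, 120)) {
    R <- rotation_about(a$axes["PROX", ], theta)
    b <- anatomic_frame(a$origin, a$axes %*% t(R), "femur")
    rot <- frame_rotation(a, b)
    expect_lt(abs(rot$total_deg - theta), 1e-9)
    expect_lt(abs(rot$about_PROX_deg - theta), 1e-9)
  }
  # rotation about an axis perpendicular to PROX has no axial component
  Rp <- rotation_about(a$axes["ML", ], 20)
  b <- anatomic_frame(a$origin, a$axes %*% t(Rp), "femur")
  rot <- frame_rotation(a, b)
  expect_lt(abs(rot$total_deg - 20), 1e-9)
  expect_lt(abs(rot$about_PROX_deg), 1e-9)
})

test_that("total rotation angle matches a quaternion oracle", {
  set.seed(13)
  base <- identity_frame()
  for (rep in 1:200) {
    R <- random_rotation()
    b <- anatomic_frame(c(0, 0, 0), diag(3) %*% t(R), "femur")
    expect_lt(abs(frame_rotation(base, b)$total_deg -
                    quaternion_angle_deg(R)), 1e-9)
  }
})

test_that("world/anatomic mapping round trips and hits the axes", {
  set.seed(19)
  lm <- random_landmarks()
  f <- femoral_frame(lm)
  expect_lt(max(abs(world_to_anatomic(f$origin, f))), 1e-9)
  p <- f$origin + 10 * f$axes["ML", ]
  expect_lt(max(abs(world_to_anatomic(p, f) - c(10, 0, 0))), 1e-9)
  pts <- matrix(runif(60, -100, 100), ncol = 3)
  back <- world_to_anatomic(anatomic_to_world(pts, f), f)
  expect_lt(max(abs(back - pts)), 1e-9)
})

test_that("landmark and frame JSON files round trip", {
  lm <- landmark_set(medial_epicondyle = c(-40, 1, 2),
                     lateral_epicondyle = c(40, -1, 3),
                     femoral_head_centre = c(5, 6, 400),
                     talus_centre = c(0, 2, -380), side = "right")
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_equal(back$medial_epicondyle, lm$medial_epicondyle)
  expect_equal(back$talus_centre, lm$talus_centre)
  expect_identical(back$side, "right")

  f <- femoral_frame(lm)
  fpath <- withr::local_tempfile(fileext = ".json")
  write_frame(f, fpath)
  f2 <- read_frame(fpath)
  expect_equal(f2$axes, f$axes)
  expect_equal(f2$origin, f$origin)

  expect_error(read_landmarks(withr::local_tempfile()), "not found")
})

test_that("landmark sets from fitted head-surface points work end to end", {
  set.seed(23)
  centre <- c(10, -5, 420)
  u <- matrix(rnorm(50 * 3), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * 24, 2, centre, "+")
  lm <- landmark_set(medial_epicondyle = c(-38, 0, 0),
                     lateral_epicondyle = c(42, 0, 0),
                     head_surface_points = pts, side = "left")
  expect_lt(max(abs(lm$femoral_head_centre - centre)), 1e-6)
  expect_equal(attr(lm, "head_fit_radius"), 24, tolerance = 1e-6)
  expect_s3_class(femoral_frame(lm), "anatomic_frame")
})
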