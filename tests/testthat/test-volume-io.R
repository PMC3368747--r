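test_that("NIfTI and NRRD round trips preserve voxels and affine", {
  set.seed(11)
  vox <- array(rnorm(8 * 8 * 8), dim = c(8, 8, 8))
  th <- 30 * pi / 180
  aff <- diag(4)
  aff[1:3, 1:3] <- matrix(c(cos(th), sin(th), 0,
                            -sin(th), cos(th), 0,
                            0, 0, 1), 3, 3) %*% diag(c(1, 1, 2))
  aff[1:3, 4] <- c(5.5, -3.25, 7)
  vol <- image_volume(vox, aff, "CT")
  for (ext in c(".nii", ".nii.gz", ".nrrd")) {
    path <- withr::local_tempfile(fileext = ext)
    write_volume(vol, path)
    back <- read_volume(path, "CT")
    expect_identical(back$voxels + 0, vox, label = ext)
    expect_lt(max(abs(back$affine - aff)), 1e-6)
  }
})

test_that("volume reading rejects unknown extensions and 2D payloads", {
  expect_error(read_volume("foo.xyz"), "not found")
  vol2d <- RNifti::asNifti(matrix(rnorm(16), 4, 4))
  path <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(vol2d, path)
  expect_error(read_volume(path, "CT"), "3D")
  expect_error(write_volume(image_volume(array(1, c(2, 2, 2)), diag(4), "CT"),
                            withr::local_tempfile(fileext = ".xyz")),
               "extension")
})

test_that("image_volume enforces its invariants", {
  expect_error(image_volume(array(1, c(2, 2)), diag(4), "CT"), "3D")
  bad <- diag(4); bad[1, 1] <- 0
  expect_error(image_volume(array(1, c(2, 2, 2)), bad, "CT"), "invertible")
  expect_error(image_volume(array(-1, c(2, 2, 2)), diag(4), "SPECT"),
               "non-negative")
  vol <- image_volume(array(1, c(2, 3, 4)), diag(c(1, 2, 3, 1)), "SPECT")
  expect_equal(vol$spacing, c(1, 2, 3))
})

test_that("DICOM series round trip reproduces voxels and geometry", {
  set.seed(21)
  vox <- array(sample(0:3000, 12 * 10 * 4, TRUE) - 1024, dim = c(12, 10, 4))
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(c(1, 1, 2))
  aff[1:3, 4] <- c(-20, 13, 5)
  vol <- image_volume(vox, aff, "CT")
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  back <- read_dicom_series(dir)
  expect_equal(back$voxels, vox + 0)
  expect_equal(back$affine, aff)
  expect_identical(back$modality, "CT")
})

test_that("DICOM reader sorts shuffled slices by position along the normal", {
  set.seed(22)
  vox <- array(sample(0:500, 6 * 6 * 5, TRUE), dim = c(6, 6, 5))
  vol <- image_volume(vox, diag(c(1, 1, 3, 1)), "SPECT")
  sorted_dir <- withr::local_tempdir()
  write_dicom_series(vol, sorted_dir)
  shuffled_dir <- withr::local_tempdir()
  files <- list.files(sorted_dir, full.names = TRUE)
  # rename so lexicographic file order disagrees with slice order
  new_names <- file.path(shuffled_dir,
                         sprintf("s%d.dcm", rev(seq_along(files))))
  file.copy(files, new_names)
  expect_identical(read_dicom_series(shuffled_dir)$voxels,
                   read_dicom_series(sorted_dir)$voxels)
})

test_that("DICOM reader rejects mixed series and non-uniform slice gaps", {
  vox <- array(0:99, dim = c(5, 5, 4))
  vol <- image_volume(vox, diag(c(1, 1, 2, 1)), "SPECT")
  dir <- withr::local_tempdir()
  write_dicom_series(vol, dir)
  other <- withr::local_tempdir()
  write_dicom_series(vol, other, series_uid = "1.2.826.0.1.3680043.9999.2")
  file.copy(file.path(other, "slice_0001.dcm"),
            file.path(dir, "extra.dcm"))
  expect_error(read_dicom_series(dir), "SeriesInstanceUID")

  # non-uniform gap: drop a middle slice
  gap_dir <- withr::local_tempdir()
  write_dicom_series(vol, gap_dir)
  file.remove(file.path(gap_dir, "slice_0002.dcm"))
  expect_error(read_dicom_series(gap_dir), "non-uniform")
})

test_that("identity-frame resampling reproduces the volume", {
  set.seed(31)
  vox <- array(rnorm(10 * 10 * 10), dim = c(10, 10, 10))
  aff <- diag(4); aff[1:3, 4] <- c(3, -2, 8)
  vol <- image_volume(vox, aff, "CT")
  frame <- identity_frame()
  rs <- resample_to_frame(vol, frame, spacing = 1,
                          bounds = list(min = c(3, -2, 8),
                                        max = c(12, 7, 17)))
  expect_equal(dim(rs$voxels), c(10L, 10L, 10L))
  expect_lt(max(abs(rs$voxels - vox)), 1e-9)
})

test_that("resampling a linear ramp through a rotated frame matches the analytic ramp", {
  # volume value = world x coordinate (a linear field, exactly representable
  # by trilinear interpolation); the frame is rotated 90 degrees about z and
  # centred inside the grid, so every sample is interior
  n <- 21L
  vox <- array(rep(0:(n - 1), n * n), dim = c(n, n, n))
  vol <- image_volume(vox, diag(4), "CT")
  origin <- c(10, 10, 10)
  frame <- anatomic_frame(origin, rotation_about(c(0, 0, 1), 90), "femur")
  rs <- resample_to_frame(vol, frame, spacing = 1,
                          bounds = list(min = c(-5, -5, -5),
                                        max = c(5, 5, 5)))
  # expected: value at frame coord f is the world x of origin + f mapped
  # through the rotated axes
  d <- dim(rs$voxels)
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  fpts <- sweep(idx, 2, c(-5, -5, -5), "+")
  wx <- anatomic_to_world(fpts, frame)[, 1]
  expect_lt(max(abs(as.numeric(rs$voxels) - wx)), 1e-6)
})

test_that("resampling rejects non-orthonormal frames and degenerate bounds", {
  vol <- image_volume(array(1, c(4, 4, 4)), diag(4), "CT")
  bad_axes <- diag(3) * 2
  expect_error(anatomic_frame(c(0, 0, 0), bad_axes, "femur"), "orthonormal")
  frame <- identity_frame()
  expect_error(resample_to_frame(vol, frame, 1,
                                 list(min = c(0, 0, 0), max = c(0, 1, 1))),
               "non-degenerate")
  expect_error(resample_to_frame(vol, frame, -1,
                                 list(min = c(0, 0, 0), max = c(1, 1, 1))),
               "positive")
})

test_that("out-of-extent samples fill with air for CT and zero for SPECT", {
  vox <- array(500, c(3, 3, 3))
  ct <- image_volume(vox, diag(4), "CT")
  sp <- image_volume(vox, diag(4), "SPECT")
  far <- matrix(c(100, 100, 100), 1)
  expect_equal(sample_volume(ct, far), -1024)
  expect_equal(sample_volume(sp, far), 0)
})

test_that("mean intensity of a smooth field is preserved by resampling", {
  # smooth blob sampled on a 1 mm grid; rotating the sampling frame must
  # not change the region mean appreciably (pose-independence basis)
  n <- 25L
  g <- seq(-12, 12, length.out = n)
  f <- array(0, dim = c(n, n, n))
  for (k in 1:n) {
    f[, , k] <- outer(g, g, function(x, y) {
      1000 * exp(-(x^2 + y^2 + g[k]^2) / 60)
    })
  }
  aff <- diag(4); aff[1:3, 4] <- -12
  vol <- image_volume(f, aff, "SPECT")
  frame <- anatomic_frame(c(0, 0, 0), rotation_about(c(1, 1, 1), 30),
                          "femur")
  rs <- resample_to_frame(vol, frame, 1,
                          list(min = c(-6, -6, -6), max = c(6, 6, 6)))
  direct <- resample_to_frame(vol, identity_frame(), 1,
                              list(min = c(-6, -6, -6), max = c(6, 6, 6)))
  expect_lt(abs(mean(rs$voxels) / mean(direct$voxels) - 1), 0.01)
})
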