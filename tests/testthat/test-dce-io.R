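test_that("series write/read round-trips voxel data and spacing", {
  s <- uniform_series(c(100, 140, 150, 145), dims = c(6, 5, 4))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_dce_series(s, path)
  s2 <- read_dce_series(path)
  expect_identical(dim(s2$voxels), dim(s$voxels))
  expect_equal(s2$voxels, s$voxels, tolerance = 0)
  expect_equal(c(s2$dx, s2$dy, s2$slice_th), c(s$dx, s$dy, s$slice_th),
               tolerance = 1e-6)
  expect_equal(s2$times, s$times)
  expect_identical(s2$n_post, 3L)
})

test_that("series constructor and reader reject malformed input", {
  vox <- array(1, dim = c(4, 4, 2, 4))
  expect_error(dce_series(vox, dx = 0, dy = 1, slice_th = 1, times = 0:3),
               "dx")
  expect_error(dce_series(vox[, , , 1:2], dx = 1, dy = 1, slice_th = 1,
                          times = 0:1),
               "pre \\+ post")
  expect_error(dce_series(vox, dx = 1, dy = 1, slice_th = 1,
                          times = c(0, 2, 1, 3)),
               "strictly increasing")
  neg <- vox; neg[1, 1, 1, 1] <- -1
  expect_error(dce_series(neg, dx = 1, dy = 1, slice_th = 1, times = 0:3),
               "non-negative")

  expect_error(read_dce_series(withr::local_tempfile()), "not found")
  vol3d <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(4, 4, 2))), vol3d)
  expect_error(read_dce_series(vol3d), "4D")
  two_frame <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, dim = c(4, 4, 2, 2))), two_frame)
  expect_error(read_dce_series(two_frame), "pre \\+ post")
})

test_that("mask reading enforces the parent grid and nonzero = foreground", {
  s <- uniform_series(c(100, 120, 130), dims = c(8, 8, 3))
  m <- array(FALSE, dim = c(8, 8, 3))
  m[2:4, 3:6, 2] <- TRUE
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, s, path)
  m2 <- read_mask(path, s)
  expect_identical(sum(m2), sum(m))
  expect_identical(m2, m)

  zero_path <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(array(FALSE, dim = c(8, 8, 3)), s, zero_path)
  expect_identical(sum(read_mask(zero_path, s)), 0L)

  small <- uniform_series(c(100, 120, 130), dims = c(7, 8, 3))
  expect_error(read_mask(path, small), "does not match")
})

test_that("voi enforces bounds, uniqueness and 26-connectivity", {
  grid <- c(5, 5, 5)
  expect_error(voi(matrix(numeric(0), ncol = 3), grid), "non-empty")
  expect_error(voi(rbind(c(1, 1, 1), c(1, 1, 1)), grid), "unique")
  expect_error(voi(rbind(c(0, 1, 1)), grid), "out of bounds")
  expect_error(voi(rbind(c(1, 1, 1), c(4, 4, 4)), grid), "26-connected")
  v <- voi(rbind(c(1, 1, 1), c(2, 2, 2)), grid)  # corner contact is connected
  expect_s3_class(v, "voi")
  expect_identical(v$label, "unknown")
})

test_that("feature tables round-trip numerically and refuse empty input", {
  feats <- list(
    lesions = tibble::tibble(
      lesion_id = c("a", "b", "c"), split = c("train", "train", "test"),
      label = c("benign", "malignant", "malignant"), detected = TRUE,
      n_voxels = c(10L, 12L, 9L),
      area_median = c(9.25, 16, 4) * pi, perimeter_median = c(8, 12, 6),
      compactness = c(8.123456789, 25.04, 1), eccentricity = c(0.1, 0.8, 0.3),
      bs = c(100.5, 99.1, 101.2), re_slope = c(1.234e-3, 2e-3, -1e-4),
      sod = c(250.1, 300.7, 180)),
    voxels = tibble::tibble(
      lesion_id = rep(c("a", "b"), 2), split = "train",
      label = rep(c("benign", "malignant"), 2),
      bs = c(100, 99, 101, 98), re_slope = c(1e-3, 2e-3, 1.5e-3, 2.5e-3),
      sod = c(250, 300, 260, 310))
  )
  path <- file.path(withr::local_tempdir(), "features.csv")
  write_feature_table(feats, path)
  back <- read_feature_table(path)
  expect_identical(nrow(back$lesions), 3L)
  for (col in c("area_median", "compactness", "re_slope", "sod")) {
    expect_equal(back$lesions[[col]], feats$lesions[[col]], tolerance = 1e-9)
  }
  expect_equal(back$voxels$re_slope, feats$voxels$re_slope, tolerance = 1e-9)
  expect_error(write_feature_table(list(lesions = tibble::tibble()), path),
               "nothing to write")
})

test_that("manifest round-trip resolves paths and validates labels", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(1, 1, seed = 3)
  write_cohort(co, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 2L)
  expect_true(all(file.exists(man$series)))
  expect_true(all(file.exists(man$mask)))

  bad <- utils::read.csv(file.path(dir, "manifest.csv"))
  bad$label[1] <- "suspicious"
  utils::write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_manifest(file.path(dir, "bad.csv")), "benign")
})

test_that("config merges user values over defaults", {
  cfg <- default_config()
  expect_identical(cfg$segmentation$re_threshold, 0.3)
  expect_identical(cfg$classify$confidence_factor, 0.25)
  expect_false(cfg$classify$pruned)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("segmentation:", "  struct_radius: 3", "fusion:",
               "  alpha_step: 0.1"), path)
  cfg2 <- read_config(path)
  expect_identical(cfg2$segmentation$struct_radius, 3L)
  expect_identical(cfg2$fusion$alpha_step, 0.1)
  expect_identical(cfg2$segmentation$re_threshold, 0.3)
})
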