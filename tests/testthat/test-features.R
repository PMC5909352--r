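test_that("slice area and perimeter match enumerated masks", {
  m5 <- matrix(FALSE, 6, 6); m5[2:4, 2] <- TRUE; m5[2:3, 3] <- TRUE
  expect_equal(slice_area(m5, 1, 1), 5)
  m3 <- matrix(FALSE, 4, 4); m3[1:3, 2] <- TRUE
  expect_equal(slice_area(m3, 0.5, 0.5), 0.75)
  expect_error(slice_area(matrix(FALSE, 3, 3), 1, 1), "empty")

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(slice_perimeter(single), 1L)
  block <- matrix(FALSE, 5, 5); block[2:4, 2:4] <- TRUE
  expect_identical(slice_perimeter(block), 8L)
  row3 <- matrix(FALSE, 5, 5); row3[2:4, 3] <- TRUE
  expect_identical(slice_perimeter(row3), 3L)
  # grid border counts as background: a full row is all boundary
  edge <- matrix(FALSE, 3, 3); edge[, 1] <- TRUE
  expect_identical(slice_perimeter(edge), 3L)
})

test_that("3D compactness matches enumeration on cubes", {
  g5 <- c(7, 7, 7)
  v1 <- voi(rbind(c(4, 4, 4)), g5)
  expect_equal(compactness_3d(v1, 1, 1, 1), 1)
  cube2 <- voi(as.matrix(expand.grid(x = 3:4, y = 3:4, z = 3:4)), g5)
  expect_equal(compactness_3d(cube2, 1, 1, 1), 8)
  cube3 <- voi(as.matrix(expand.grid(x = 3:5, y = 3:5, z = 3:5)), g5)
  expect_equal(compactness_3d(cube3, 1, 1, 1), 676 / 27)
  # against the independent boundary oracle for n = 4..6 cubes: S^2/V with
  # unit spacing reduces to B^2/n, and grows roughly linearly in n
  comp <- vapply(4:6, function(n) {
    g <- c(n + 4, n + 4, n + 4)
    co <- as.matrix(expand.grid(x = 2:(n + 1), y = 2:(n + 1), z = 2:(n + 1)))
    v <- voi(co, g)
    m <- mask_from_coords(co, g)
    expect_equal(compactness_3d(v, 1, 1, 1),
                 boundary_count_oracle(m)^2 / n^3)
    compactness_3d(v, 1, 1, 1)
  }, numeric(1))
  expect_true(all(diff(comp) > 0))
})

test_that("3D eccentricity is 0 for symmetric clouds and tracks axis ratios", {
  g <- c(15, 15, 15)
  cube <- voi(as.matrix(expand.grid(x = 6:8, y = 6:8, z = 6:8)), g)
  expect_equal(eccentricity_3d(cube, 1, 1, 1), 0, tolerance = 1e-12)

  # solid ellipsoid with semi-axes 5, 4, 3: ECC = sqrt(1 - (3/5)^2) = 0.8
  gg <- expand.grid(x = 1:15, y = 1:15, z = 1:15)
  inside <- ((gg$x - 8) / 5)^2 + ((gg$y - 8) / 4)^2 + ((gg$z - 8) / 3)^2 <= 1
  ell <- voi(as.matrix(gg[inside, ]), c(15, 15, 15), check_connected = FALSE)
  expect_equal(eccentricity_3d(ell, 1, 1, 1), 0.8, tolerance = 0.04)

  ball <- (gg$x - 8)^2 + (gg$y - 8)^2 + (gg$z - 8)^2 <= 36
  bv <- voi(as.matrix(gg[ball, ]), c(15, 15, 15), check_connected = FALSE)
  expect_lt(eccentricity_3d(bv, 1, 1, 1), 0.15)

  line <- voi(cbind(1:5, rep(1, 5), rep(1, 5)), c(6, 6, 6))
  expect_error(eccentricity_3d(line, 1, 1, 1), "degenerate")
})

test_that("morphological vector uses slice-wise medians and whole-VOI 3D terms", {
  s <- uniform_series(c(100, 120, 130), dims = c(9, 9, 5))
  block <- voi(as.matrix(expand.grid(x = 4:6, y = 4:6, z = 3)), c(9, 9, 5))
  mv <- morph_feature_vector(block, s)
  expect_equal(mv$area_median, 9)
  expect_equal(mv$perimeter_median, 8)

  # slice areas {4, 9, 25} -> median 9 (odd count)
  odd <- rbind(as.matrix(expand.grid(x = 4:5, y = 4:5, z = 1)),
               as.matrix(expand.grid(x = 4:6, y = 4:6, z = 2)),
               as.matrix(expand.grid(x = 3:7, y = 3:7, z = 3)))
  v_odd <- voi(odd, c(9, 9, 5))
  expect_equal(morph_feature_vector(v_odd, s)$area_median, 9)

  # slice areas {4, 16} -> median 10 (even count: mean of middle two)
  even <- rbind(as.matrix(expand.grid(x = 4:5, y = 4:5, z = 1)),
                as.matrix(expand.grid(x = 3:6, y = 3:6, z = 2)))
  v_even <- voi(even, c(9, 9, 5))
  expect_equal(morph_feature_vector(v_even, s)$area_median, 10)
})

test_that("morphological features are invariant to rigid voxel translation", {
  s <- uniform_series(c(100, 120, 130), dims = c(16, 16, 10))
  base <- as.matrix(expand.grid(x = 3:6, y = 3:5, z = 2:4))
  v1 <- voi(base, c(16, 16, 10))
  v2 <- voi(sweep(base, 2, c(5, 6, 3), "+"), c(16, 16, 10))
  expect_equal(morph_feature_vector(v1, s), morph_feature_vector(v2, s))
})

test_that("dynamic feature formulas match hand evaluation", {
  t3 <- c(60, 120, 180)
  expect_equal(basal_signal(tic(100, c(110, 120), t3[1:2])), 100)
  expect_warning(basal_signal(tic(0, c(10, 20), t3[1:2])), "undefined")

  curve <- tic(100, c(150, 120, 130), t3)
  expect_equal(relative_enhancement(curve, 1), 0.5)
  expect_equal(relative_enhancement(tic(100, c(100, 100), t3[1:2]), 2), 0)
  expect_error(relative_enhancement(tic(0, c(10, 20), t3[1:2]), 1), "undefined")

  # RE = [0.1, 0.2, 0.3] at t = 60, 120, 180 -> slope 0.1/60
  rising <- tic(100, c(110, 120, 130), t3)
  expect_equal(re_slope(rising), 0.1 / 60, tolerance = 1e-12)
  expect_equal(re_slope(tic(100, c(120, 120, 120), t3)), 0)
  two <- tic(100, c(110, 140), c(60, 180))
  expect_equal(re_slope(two), (0.4 - 0.1) / 120)
})

test_that("per-voxel dynamic features have the right cardinality and degeneracies", {
  s <- uniform_series(c(100, 100, 100, 100), dims = c(5, 5, 2))
  co <- as.matrix(expand.grid(x = 1:5, y = 1:2, z = 1))
  v <- voi(co, c(5, 5, 2))
  dyn <- dyn_feature_vector(v, s)
  expect_identical(nrow(dyn), 10L)
  expect_equal(dyn$sod, dyn$bs)      # flat series: SOD = BS
  expect_equal(dyn$re_slope, rep(0, 10))

  # intensity scaling: bs and sod scale, re_slope invariant
  s2 <- curve_series(list("1,1,1" = c(100, 140, 150, 145)), dims = c(2, 2, 1),
                     n_frames = 4)
  v1 <- voi(rbind(c(1, 1, 1)), c(2, 2, 1))
  d1 <- dyn_feature_vector(v1, s2)
  s3 <- dce_series(s2$voxels * 2, s2$dx, s2$dy, s2$slice_th, s2$times)
  d2 <- dyn_feature_vector(v1, s3)
  expect_equal(d2$bs, 2 * d1$bs)
  expect_equal(d2$sod, 2 * d1$sod)
  expect_equal(d2$re_slope, d1$re_slope)

  # constant time offset leaves the slope unchanged
  s4 <- dce_series(s2$voxels, s2$dx, s2$dy, s2$slice_th, s2$times + 30)
  expect_equal(dyn_feature_vector(v1, s4)$re_slope, d1$re_slope)
})

test_that("malignant-archetype voxels show faster wash-in and larger SOD than benign", {
  times <- seq(0, 504, by = 56)
  mal <- kinetic_curve(kinetic_params(bs0 = 100, amp = 1, k_in = 0.03,
                                      k_out = 0.002), times)
  ben <- kinetic_curve(kinetic_params(bs0 = 100, amp = 1, k_in = 0.008,
                                      k_out = 0), times)
  # same amplitude: the wash-out curve travels further (up and down)
  expect_gt(sod_voxel(mal), sod_voxel(ben))
  # faster uptake: higher relative enhancement at the first post scan
  expect_gt(relative_enhancement(mal, 1), relative_enhancement(ben, 1))
})
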