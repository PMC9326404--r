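test_that("panel calibration is exact on noiseless scenes and scale invariant", {
  cfg <- noiseless_scene()
  sc <- render_scene(cfg, 1.4, seed = 11)
  refl <- calibrate_reflectance(sc$cube, panel_reflectance = cfg$panel_reflectance)
  # panel pixels map to the nominal panel reflectance in every band
  pv <- apply(refl$values, 3, function(m) mean(m[refl$panel_region]))
  expect_equal(as.numeric(pv), rep(cfg$panel_reflectance, 128), tolerance = 1e-12)
  # leaf pixel reflectance matches the generator ground truth
  # (dark current enters both panel and leaf; supply it to the calibration)
  refl2 <- calibrate_reflectance(sc$cube, panel_reflectance = cfg$panel_reflectance,
                                 dark_current = cfg$dark_current)
  px <- which(sc$leaf_mask)[1]
  rc <- arrayInd(px, dim(sc$leaf_mask))
  got <- refl2$values[rc[1], rc[2], ]
  want <- (sc$cube$values[rc[1], rc[2], ] - cfg$dark_current) / cfg$illumination_gain
  expect_equal(got, want, tolerance = 1e-12)
  # doubling all DN leaves the no-offset ratio unchanged
  cube2 <- hypercube(sc$cube$values * 2, sc$cube$grid, "dn",
                     sc$cube$panel_region, sc$cube$background_region)
  refl3 <- calibrate_reflectance(cube2, panel_reflectance = cfg$panel_reflectance)
  expect_equal(refl3$values, refl$values, tolerance = 1e-12)
  # degenerate panel errors name the band
  bad <- sc$cube
  bad$values[, , 5][bad$panel_region] <- 0
  bad <- hypercube(bad$values, bad$grid, "dn", bad$panel_region)
  expect_error(calibrate_reflectance(bad, panel_reflectance = 0.6,
                                     dark_current = cfg$dark_current), "5")
})

test_that("segmentation thresholds at 0.25, drops panel, keeps largest component", {
  g <- band_grid(4, 790, 5)  # 790..805, nearest to 800 is band 3
  vals <- array(0.05, c(8, 8, 4))
  vals[2:4, 2:4, ] <- 0.28      # leaf blob (9 px)
  vals[7, 7, ] <- 0.30          # speckle (1 px)
  vals[1, 8, ] <- 0.20          # below threshold
  cube <- hypercube(vals, g, "reflectance")
  m <- segment_leaf(cube)
  expect_true(all(m[2:4, 2:4]))
  expect_false(m[7, 7])     # smaller component dropped
  expect_false(m[1, 8])     # background
  expect_equal(sum(m), 9)
  # boundary: exactly 0.25 is leaf, 0.2 is background plate
  vals2 <- array(0.2, c(4, 4, 4)); vals2[2, 2, ] <- 0.25
  m2 <- segment_leaf(hypercube(vals2, g, "reflectance"))
  expect_true(m2[2, 2]); expect_equal(sum(m2), 1)
  # all-background cube errors
  vals3 <- array(0.1, c(4, 4, 4))
  expect_error(segment_leaf(hypercube(vals3, g, "reflectance")), "empty mask")
})

test_that("segmentation recovers the generator mask with Jaccard >= 0.95", {
  cfg <- test_scene()
  for (seed in c(5, 17)) {
    sc <- render_scene(cfg, 1.0, seed = seed)
    refl <- calibrate_reflectance(sc$cube, panel_reflectance = cfg$panel_reflectance)
    m <- segment_leaf(refl)
    jac <- sum(m & sc$leaf_mask) / sum(m | sc$leaf_mask)
    expect_gte(jac, 0.95)
  }
})

test_that("mean_spectrum matches a brute-force per-band loop", {
  set.seed(42)
  g <- band_grid(6, 400, 10)
  vals <- array(runif(5 * 4 * 6), c(5, 4, 6))
  cube <- hypercube(vals, g, "reflectance")
  mask <- matrix(runif(20) > 0.5, 5, 4)
  mask[1, 1] <- TRUE
  got <- mean_spectrum(cube, mask)
  want <- vapply(1:6, function(b) {
    s <- 0; n <- 0
    for (r in 1:5) for (c in 1:4) if (mask[r, c]) { s <- s + vals[r, c, b]; n <- n + 1 }
    s / n
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  # constant cube and single-pixel identities
  cube_c <- hypercube(array(0.3, c(5, 4, 6)), g, "reflectance")
  expect_equal(mean_spectrum(cube_c, mask), rep(0.3, 6))
  one <- matrix(FALSE, 5, 4); one[2, 3] <- TRUE
  expect_equal(mean_spectrum(cube, one), vals[2, 3, ])
  expect_error(mean_spectrum(cube, matrix(TRUE, 3, 3)), "shape")
  expect_error(mean_spectrum(cube, matrix(FALSE, 5, 4)), "empty")
})

test_that("lab potassium formula matches hand evaluation and is linear", {
  expect_equal(lab_k_percent(0, 100, 10, 0.5), 0)
  expect_equal(lab_k_percent(50, 100, 10, 0.5), 10)
  expect_equal(lab_k_percent(25, 50, 4, 1.0), 0.5)
  # linear in rho and in 1/m
  expect_equal(lab_k_percent(100, 100, 10, 0.5), 2 * lab_k_percent(50, 100, 10, 0.5))
  expect_equal(lab_k_percent(50, 100, 10, 0.25), 2 * lab_k_percent(50, 100, 10, 0.5))
  expect_error(lab_k_percent(50, 100, 10, 0), "mass")
})
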