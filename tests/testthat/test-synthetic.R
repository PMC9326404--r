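test_that("band grid reproduces the sensor layout and trims to 106 bands", {
  g <- band_grid()
  expect_length(g, 128)
  expect_equal(as.numeric(g[1]), 376)
  expect_equal(as.numeric(g[length(g)]), 1036.4)
  expect_equal(sum(g >= 400 & g <= 950), 106)
  g2 <- band_grid(2, 400, 5.2)
  expect_equal(as.numeric(g2), c(400, 405.2))
  expect_error(band_grid(128, 376, 0), "spacing")
  expect_error(band_grid(1), "n_bands")
})

test_that("trim_bands keeps closed-interval bands, is idempotent", {
  g <- structure(c(399, 400, 950, 951), spacing = 1, class = "band_grid")
  tr <- trim_bands(seq_len(4), g)
  expect_equal(as.numeric(tr$grid), c(400, 950))
  expect_equal(tr$x, c(2L, 3L))
  # exact-center single band
  g3 <- band_grid(10, 400, 5)
  tr1 <- trim_bands(seq_len(10), g3, 405, 405)
  expect_length(tr1$x, 1)
  # idempotent
  tr2 <- trim_bands(tr$x, tr$grid)
  expect_equal(tr2$x, tr$x)
  expect_equal(as.numeric(tr2$grid), as.numeric(tr$grid))
  expect_error(trim_bands(1:4, g, 500, 600), "no band centers")
})

test_that("reflectance model has green-vegetation shape and a negative NIR-K link", {
  g <- band_grid()
  truth <- ground_truth_params()
  r <- reflectance_model(1.5, g, truth)
  at <- function(nm) r[nearest_band(g, nm)]
  expect_gt(at(550), at(450))
  expect_gt(at(550), at(680))
  # monotone red edge rise
  red_edge <- r[g >= 690 & g <= 760]
  expect_true(all(diff(red_edge) > 0))
  # plateau decreasing in K: difference equals configured slope x delta-K
  nir <- as.numeric(g) >= 760 & as.numeric(g) <= 950
  r_lo <- reflectance_model(1.0, g, truth)
  r_hi <- reflectance_model(2.0, g, truth)
  expect_gt(mean(r_lo[nir]), mean(r_hi[nir]))
  plateau_at <- function(k) reflectance_model(k, g, truth)[nearest_band(g, 900)]
  sdv <- 0.5
  expect_equal(plateau_at(1.5 - sdv) - plateau_at(1.5 + sdv),
               truth$nir_slope * 2 * sdv, tolerance = 1e-6)
  expect_error(reflectance_model(99, g, truth), "outside configured range")
})

test_that("rendered scenes are seed-deterministic with sane regions", {
  cfg <- test_scene()
  s1 <- render_scene(cfg, 1.2, seed = 7)
  s2 <- render_scene(cfg, 1.2, seed = 7)
  expect_identical(s1$cube$values, s2$cube$values)
  expect_identical(s1$leaf_mask, s2$leaf_mask)
  s3 <- render_scene(cfg, 1.2, seed = 8)
  expect_false(identical(s1$cube$values, s3$cube$values))
  # noiseless sensor model: DN/gain - dark/gain equals reflectance exactly
  cfg0 <- noiseless_scene()
  s0 <- render_scene(cfg0, 1.2, seed = 7)
  refl <- (s0$cube$values - cfg0$dark_current) / cfg0$illumination_gain
  b800 <- nearest_band(cfg0$grid, 800)
  bg <- s0$cube$background_region
  expect_lt(max(refl[, , b800][bg]), 0.25)
  panel_vals <- apply(s0$cube$values, 3, function(m) mean(m[s0$cube$panel_region]))
  expect_equal(as.numeric(panel_vals),
               rep(cfg0$panel_reflectance * cfg0$illumination_gain + cfg0$dark_current, 128),
               tolerance = 1e-9)
})

test_that("low-K leaves show higher GLCM contrast at 800 nm than high-K (same seed)", {
  cfg <- test_scene()
  img_for <- function(k) {
    sc <- render_scene(cfg, k, seed = 21)
    refl <- calibrate_reflectance(sc$cube, panel_reflectance = cfg$panel_reflectance)
    img <- band_image(refl, 800)
    px <- img[sc$leaf_mask]
    scaled <- matrix(0L, nrow(img), ncol(img))
    scaled[sc$leaf_mask] <- as.integer(round((px - min(px)) / diff(range(px)) * 255))
    list(img = scaled, mask = sc$leaf_mask)
  }
  lo <- img_for(0.5); hi <- img_for(2.2)
  con_lo <- glcm_stats(glcm_matrix(lo$img, lo$mask, 0))$CON
  con_hi <- glcm_stats(glcm_matrix(hi$img, hi$mask, 0))$CON
  expect_gt(con_lo, con_hi)
})

test_that("campaigns have the configured size, K ranges and seed determinism", {
  cfg <- scene_config()          # full default: 3 stages x 60 leaves
  camp <- generate_campaign(cfg, seed = 2)
  expect_equal(nrow(camp$samples), 180)
  expect_equal(as.numeric(table(camp$samples$stage)),
               c(60, 60, 60))
  boll_k <- camp$samples$k_percent[camp$samples$stage == "boll"]
  expect_true(all(boll_k >= 0.40 & boll_k <= 2.30))
  camp2 <- generate_campaign(cfg, seed = 2)
  expect_identical(camp$samples$k_percent, camp2$samples$k_percent)
  expect_error(generate_campaign(scene_config(n_leaves_per_stage = 2L), 1),
               ">= 3 leaves")
})

test_that("stage K moments converge to the configured values at n = 600", {
  cfg <- scene_config(n_leaves_per_stage = 600L)
  for (st in names(cfg$stage_k_params)) {
    p <- cfg$stage_k_params[[st]]
    camp <- generate_campaign(cfg, seed = 1, stages = st)
    k <- camp$samples$k_percent
    se_mean <- p[["sd"]] / sqrt(600)
    se_sd <- p[["sd"]] / sqrt(2 * 600)
    expect_lt(abs(mean(k) - p[["mean"]]), 3 * se_mean)
    expect_lt(abs(sd(k) - p[["sd"]]), 3 * se_sd)
    expect_true(all(k >= p[["min"]] & k <= p[["max"]]))
  }
})

test_that("K correlates negatively with mean NIR reflectance over a stage", {
  camp <- generate_campaign(test_scene(), seed = 3, stages = "boll",
                            keep_cubes = TRUE)
  cs <- campaign_spectra(camp)
  nir <- rowMeans(cs$spectra[, as.numeric(cs$grid) >= 760 &
                               as.numeric(cs$grid) <= 950])
  r <- cor(camp$samples$k_percent, nir)
  expect_lt(r, 0)
  expect_gt(abs(r), 0.5)
})
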