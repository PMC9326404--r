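test_that("GLCM matches hand enumeration on the 2x2 example", {
  img <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # rows: [0 1; 0 1]
  P <- glcm_matrix(img, angle = 0, levels = 2L)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)
  st <- glcm_stats(P)
  expect_equal(st$ENE, 0.5)
  expect_equal(st$ENT, log(2))
  expect_equal(st$CON, 1)
  expect_equal(st$COR, -1)
})

test_that("constant regions give delta GLCMs: ENE 1, ENT 0, CON 0", {
  img <- matrix(7L, 5, 5)
  for (ang in c(0, 45, 90, 135)) {
    P <- glcm_matrix(img, angle = ang, levels = 16L)
    expect_equal(P[8, 8], 1)
    st <- glcm_stats(P)
    expect_equal(st$ENE, 1)
    expect_equal(st$ENT, 0)
    expect_equal(st$CON, 0)
    expect_true(st$degenerate)
    expect_equal(st$COR, 0)   # degenerate marginals -> flagged zero
  }
})

test_that("GLCM and its statistics match brute-force enumeration on 100 random masked images", {
  set.seed(303)
  for (rep in 1:100) {
    rows <- sample(4:16, 1); cols <- sample(4:16, 1)
    rmi <- random_masked_image(rows, cols, levels = 16L)
    ang <- sample(c(0, 45, 90, 135), 1)
    P_got <- glcm_matrix(rmi$image, rmi$mask, ang, levels = 16L)
    P_want <- oracle_glcm(rmi$image, rmi$mask, ang, levels = 16L)
    expect_lt(max(abs(P_got - P_want)), 1e-12)
    st_got <- glcm_stats(P_got)
    st_want <- oracle_glcm_stats(P_want)
    for (nm in c("ENE", "ENT", "CON", "COR", "MEA", "VAR"))
      expect_lt(abs(st_got[[nm]] - st_want[[nm]]), 1e-12)
  }
})

test_that("an L-shaped mask counts only pairs inside the mask", {
  img <- matrix(sample.int(4, 36, replace = TRUE) - 1L, 6, 6)
  mask <- matrix(FALSE, 6, 6)
  mask[, 1:2] <- TRUE; mask[5:6, ] <- TRUE    # L shape, arms two pixels wide
  for (ang in c(0, 45, 90, 135)) {
    got <- glcm_matrix(img, mask, ang, levels = 4L)
    want <- oracle_glcm(img, mask, ang, levels = 4L)
    expect_equal(got, want, tolerance = 1e-14)
  }
})

test_that("rotating an image by 90 degrees swaps 0- and 90-degree features", {
  set.seed(11)
  img <- matrix(sample.int(8, 64, replace = TRUE) - 1L, 8, 8)
  # counterclockwise rotation: horizontal neighbours become vertical
  rot <- t(img)[ncol(img):1, ]
  P0 <- glcm_matrix(img, angle = 0, levels = 8L)
  P90r <- glcm_matrix(rot, angle = 90, levels = 8L)
  expect_equal(P0, P90r, tolerance = 1e-14)
  s0 <- glcm_stats(P0); s90 <- glcm_stats(P90r)
  expect_equal(s0$CON, s90$CON)
  expect_equal(s0$COR, s90$COR)
})

test_that("texture_features returns the named 24-vector with angle aggregates", {
  set.seed(12)
  img <- matrix(sample.int(256, 400, replace = TRUE) - 1L, 20, 20)
  tf <- texture_features(img, wavelength_nm = 641)
  expect_length(tf, 24)
  expect_true("641 nm-CON-135°" %in% names(tf))
  expect_true("641 nm-MEA (CON)" %in% names(tf))
  expect_true("641 nm-VAR (COR)" %in% names(tf))
  expect_false(anyDuplicated(names(tf)) > 0)
  # aggregates match their per-angle parts
  cons <- tf[sprintf("641 nm-CON-%d°", c(0, 45, 90, 135))]
  expect_equal(unname(tf["641 nm-MEA (CON)"]), mean(cons))
  expect_equal(unname(tf["641 nm-VAR (CON)"]), mean((cons - mean(cons))^2))
  # constant region: all CON zero, all ENE one
  tfc <- texture_features(matrix(3L, 6, 6), wavelength_nm = 500)
  expect_true(all(tfc[grepl("-CON-", names(tfc))] == 0))
  expect_true(all(tfc[grepl("-ENE-", names(tfc))] == 1))
})

test_that("isotropic texture has small across-angle variance relative to its mean", {
  set.seed(13)
  img <- matrix(sample.int(64, 60 * 60, replace = TRUE) - 1L, 60, 60)
  tf <- texture_features(img, wavelength_nm = 700, levels = 64L)
  expect_lt(sqrt(tf[["700 nm-VAR (CON)"]]), 0.05 * tf[["700 nm-MEA (CON)"]])
})

test_that("color moments match hand evaluation", {
  expect_equal(unname(color_moments(matrix(c(0, 2), 1, 2))),
               c(1, 1, 0))
  expect_equal(unname(color_moments(matrix(c(0, 0, 3), 1, 3))),
               c(1, sqrt(2), 2^(1 / 3)))
  expect_equal(unname(color_moments(matrix(5, 3, 3))), c(5, 0, 0))
  # MEA/VAR agree with direct mean and population-std oracles
  set.seed(14)
  img <- matrix(runif(100, 0, 255), 10, 10)
  mask <- matrix(runif(100) > 0.4, 10, 10); mask[1, 1] <- TRUE
  cm <- color_moments(img, mask)
  px <- img[mask]
  expect_equal(unname(cm[1]), mean(px), tolerance = 1e-12)
  expect_equal(unname(cm[2]), sqrt(mean((px - mean(px))^2)), tolerance = 1e-12)
  expect_error(color_moments(img, matrix(FALSE, 10, 10)), "empty")
})

test_that("feature screening keeps perfect correlates and controls the null rate", {
  set.seed(15)
  n <- 60
  k <- runif(n, 0.4, 2.3)
  # perfect correlate plus noise columns
  tab <- cbind(k_feature = k, matrix(rnorm(n * 30), n,
                                     dimnames = list(NULL, paste0("noise", 1:30))))
  sel <- screen_image_features(tab, k, seed = 1)
  expect_true("k_feature" %in% sel$selected_names)
  # pure-noise: about 5% survive stage 1 across repetitions
  rates <- vapply(1:30, function(s) {
    set.seed(s)
    tabn <- matrix(rnorm(n * 40), n)
    mean(apply(tabn, 2, function(col) cor.test(col, k)$p.value) < 0.05)
  }, numeric(1))
  expect_lt(mean(rates), 0.10)
  expect_gt(mean(rates), 0.01)
  # all-noise screening returns an empty selection with a warning
  set.seed(16)
  tab2 <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("n", 1:5)))
  p <- apply(tab2, 2, function(col) cor.test(col, k)$p.value)
  if (all(p >= 0.05))
    expect_warning(screen_image_features(tab2, k, seed = 1), "no feature")
})
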