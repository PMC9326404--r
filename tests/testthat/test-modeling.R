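test_that("concentration-gradient split follows the middle-of-three rule", {
  sp <- concentration_gradient_split(c(1, 2, 3, 4, 5, 6))
  expect_equal(sp$validation_idx, c(2, 5))
  expect_equal(sort(c(sp$calibration_idx, sp$validation_idx)), 1:6)
  # 60 samples -> 40/20, extremes in calibration, validation range covered
  set.seed(21)
  for (rep in 1:5) {
    k <- runif(60, 0.4, 2.3)
    sp <- concentration_gradient_split(k)
    expect_length(sp$calibration_idx, 40)
    expect_length(sp$validation_idx, 20)
    expect_length(intersect(sp$calibration_idx, sp$validation_idx), 0)
    expect_true(which.min(k) %in% sp$calibration_idx)
    expect_true(which.max(k) %in% sp$calibration_idx)
    expect_gte(min(k[sp$validation_idx]), min(k[sp$calibration_idx]))
    expect_lte(max(k[sp$validation_idx]), max(k[sp$calibration_idx]))
  }
  expect_error(concentration_gradient_split(c(1, 2)), ">= 3")
  expect_error(concentration_gradient_split(1:6, ids = c(1, 1, 2, 3, 4, 5)),
               "duplicate")
})

test_that("PLSR recovers exact linear models and matches reference fits", {
  set.seed(22)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n)
  b <- rnorm(p)
  y <- drop(X %*% b) + 2
  fit <- fit_plsr(X, y, max_lv = p, seed = 1)
  expect_equal(unname(evaluate_metrics(y, predict(fit, X))["r2"]), 1,
               tolerance = 1e-8)
  # p = 1 equals simple least squares
  x1 <- matrix(rnorm(n), n)
  y1 <- 3 * x1[, 1] + rnorm(n)
  f1 <- fit_plsr(x1, y1, seed = 1)
  ls <- coef(lm(y1 ~ x1[, 1]))
  pred <- predict(f1, x1)
  expect_equal(pred, unname(ls[1] + ls[2] * x1[, 1]), tolerance = 1e-8)
  # full-component SIMPLS coefficients equal the NIPALS oracle's
  or <- oracle_nipals_pls(X, y, p)
  cf <- pls_fit_cpp(X, y, p)
  expect_equal(unname(cf$coef[, p]), unname(or$coef), tolerance = 1e-6)
  # and a mid-rank model agrees on predictions
  or3 <- oracle_nipals_pls(X, y, 3)
  cf3 <- pls_fit_cpp(X, y, 3)
  pred_cpp <- mean(y) + drop(sweep(X, 2, colMeans(X)) %*% cf3$coef[, 3])
  expect_equal(pred_cpp, or3$predict(X), tolerance = 1e-6)
})

test_that("permuted responses give near-zero validation skill", {
  set.seed(23)
  r2s <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(60 * 20), 60)
    y <- sample(runif(60, 0.4, 2.3))
    sp <- concentration_gradient_split(y)
    fit_and_evaluate(X, y, sp, seed = s)$r2_val
  }, numeric(1))
  expect_lt(mean(r2s), 0.2)
})

test_that("metrics follow the definition formulas exactly", {
  expect_equal(unname(evaluate_metrics(c(1, 2, 3), c(1, 2, 4))),
               c(0.5, sqrt(1 / 3)))
  y <- c(0.5, 1.5, 2.5, 2)
  expect_equal(unname(evaluate_metrics(y, y)), c(1, 0))
  expect_equal(unname(evaluate_metrics(y, rep(mean(y), 4))["r2"]), 0)
  # brute-force loop oracle on random vectors
  set.seed(24)
  for (rep in 1:20) {
    yt <- rnorm(15); yp <- rnorm(15)
    ss_res <- 0; ss_tot <- 0; se <- 0
    for (i in 1:15) {
      ss_res <- ss_res + (yt[i] - yp[i])^2
      ss_tot <- ss_tot + (yt[i] - mean(yt))^2
      se <- se + (yt[i] - yp[i])^2
    }
    m <- evaluate_metrics(yt, yp)
    expect_equal(unname(m["r2"]), 1 - ss_res / ss_tot, tolerance = 1e-12)
    expect_equal(unname(m["rmse"]), sqrt(se / 15), tolerance = 1e-12)
  }
  expect_error(evaluate_metrics(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(evaluate_metrics(1:3, 1:4), "equal-length")
})

test_that("the comparison harness produces the scale and fusion surfaces", {
  set.seed(25)
  n <- 60
  k <- runif(n, 0.4, 2.3)
  sp <- concentration_gradient_split(k)
  # toy spectral sets: R plus three scales for one selector
  mk <- function() matrix(rnorm(n * 5) + k, n)
  sets <- list(cars = list(R = mk(), `CWT-1` = mk(), `CWT-2` = mk(),
                           `CWT-3` = mk()))
  color <- matrix(rnorm(n * 2) + 0.5 * k, n,
                  dimnames = list(NULL, c("500 nm-MEA", "500 nm-VAR")))
  texture <- matrix(rnorm(n * 3) + 0.5 * k, n,
                    dimnames = list(NULL, paste0("f", 1:3)))
  rep_ <- fuse_and_compare(sets, color, texture, k, sp, stage = "boll")
  expect_equal(nrow(rep_$scale_rows), 4)      # 1 + 3 scales
  expect_equal(nrow(rep_$fusion_rows), 4)     # four combinations
  expect_true(all(c("r2_cal", "rmse_cal", "r2_val", "rmse_val") %in%
                    colnames(rep_$scale_rows)))
  expect_true(startsWith(rep_$fusion_rows$feature_set[2], rep_$best_scale$feature_set))
  # degraded path: empty texture block flagged
  rep2 <- fuse_and_compare(sets, color, matrix(numeric(0), n, 0), k, sp)
  expect_true(any(grepl("degraded to spectra-only", rep2$fusion_rows$feature_set)))
  expect_error(fuse_and_compare(list(cars = list(R = mk()[1:10, ])), NULL, NULL,
                                k, sp), "misaligned")
})

test_that("noise features do not inflate validation metrics on average", {
  set.seed(26)
  deltas <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    X <- matrix(rnorm(n * 6), n)
    k <- drop(X[, 1:3] %*% c(1, 0.5, 0.3)) + rnorm(n, 0, 0.2) + 1.5
    sp <- concentration_gradient_split(k)
    base <- fit_and_evaluate(X, k, sp, seed = s)$r2_val
    noisy <- fit_and_evaluate(cbind(X, matrix(rnorm(n * 30), n)), k, sp,
                              seed = s)$r2_val
    noisy - base
  }, numeric(1))
  expect_lt(mean(deltas), 0.02)   # no systematic gain from pure noise
})
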