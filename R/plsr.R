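# seeded, balanced fold assignment reused across candidate subsets so that
# RMSECV comparisons are paired
make_folds <- function(n, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Fit a PLSR model with cross-validated latent-variable count
#'
#' Mean-centered SIMPLS regression. The number of latent variables minimizes
#' the 5-fold RMSECV, capped at `min(max_lv, p, n - ceiling(n/folds) - 1)`.
#' With `scale = TRUE` features are additionally scaled to unit variance
#' (constant columns get unit divisors); this is the default inside the
#' fusion harness, where reflectance-scale spectral features meet
#' gray-level-squared texture statistics.
#'
#' @param X calibration feature matrix (samples x features).
#' @param y potassium (%) per calibration sample.
#' @param folds cross-validation folds.
#' @param max_lv latent-variable cap.
#' @param fold_id optional explicit fold assignment (1..folds per row).
#' @param seed seed for the fold shuffle when `fold_id` is NULL.
#' @param scale unit-variance scaling of the features.
#' @return A `plsr_model`: coefficients for the chosen component count,
#'   centering/scaling constants, `n_latent`, `rmsecv` trajectory.
#' @export
fit_plsr <- function(X, y, folds = 5, max_lv = 10, fold_id = NULL, seed = NULL,
                     scale = FALSE) {
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("fit_plsr: empty feature matrix", call. = FALSE)
  if (nrow(X) < folds) stop("fit_plsr: fewer samples than folds", call. = FALSE)
  if (sd(y) == 0) stop("fit_plsr: constant response", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  x_scales <- rep(1, p)
  if (scale) {
    s <- apply(X, 2, sd)
    x_scales <- ifelse(s > 0, s, 1)
    X <- sweep(X, 2, x_scales, "/")
  }
  cap <- max(1L, min(max_lv, p, n - ceiling(n / folds) - 1L))
  if (is.null(fold_id)) fold_id <- make_folds(n, folds, seed)
  rmsecv <- rmsecv_cpp(X, y, as.integer(fold_id), as.integer(cap))
  n_latent <- which.min(rmsecv)
  fit <- pls_fit_cpp(X, y, as.integer(n_latent))
  structure(list(coefficients = fit$coef[, n_latent],
                 x_means = as.numeric(fit$x_means), y_mean = fit$y_mean,
                 x_scales = x_scales,
                 n_latent = n_latent, rmsecv = as.numeric(rmsecv),
                 feature_names = colnames(X)),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d features, %d latent variable(s), RMSECV %.4f\n",
              length(x$coefficients), x$n_latent, min(x$rmsecv)))
  invisible(x)
}

#' @param object a `plsr_model`.
#' @param newdata feature matrix with the same columns as the training data.
#' @param ... unused.
#' @rdname fit_plsr
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  newdata <- sweep(newdata, 2, object$x_scales, "/")
  as.numeric(object$y_mean +
               sweep(newdata, 2, object$x_means) %*% object$coefficients)
}

#' Coefficient of determination and root mean squared error
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` and
#' `RMSE = sqrt(mean((y - yhat)^2))`, population forms without adjustment.
#'
#' @param y_true measured values.
#' @param y_pred estimated values, same length.
#' @return Named numeric `c(r2, rmse)`.
#' @export
evaluate_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2)
    stop("evaluate_metrics: need equal-length vectors of length >= 2",
         call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop("evaluate_metrics: zero variance in y_true", call. = FALSE)
  ss_res <- sum((y_true - y_pred)^2)
  c(r2 = 1 - ss_res / ss_tot, rmse = sqrt(mean((y_true - y_pred)^2)))
}

# internal: 5-fold RMSECV of a column subset at its best latent count,
# sharing a fixed fold partition (paired comparisons across subsets)
subset_rmsecv <- function(X, y, cols, fold_id, max_lv = 10) {
  Xs <- X[, cols, drop = FALSE]
  n <- nrow(Xs)
  folds <- max(fold_id)
  cap <- max(1L, min(max_lv, length(cols), n - ceiling(n / folds) - 1L))
  min(rmsecv_cpp(Xs, y, as.integer(fold_id), as.integer(cap)))
}
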