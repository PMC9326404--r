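#' Exponentially decreasing retention ratio for CARS
#'
#' The enforced-reduction schedule `r_i = a * exp(-k * i)` with endpoint
#' constraints `r_1 = 1` and `r_N = 2/p`, i.e. the first Monte Carlo run
#' keeps every variable and the last keeps two.
#'
#' @param iteration run index `i` in 1..`n_runs`.
#' @param n_runs total Monte Carlo runs `N` (>= 2).
#' @param n_vars number of variables `p` (>= 3).
#' @return Retention fraction in (0, 1].
#' @export
edf_ratio <- function(iteration, n_runs, n_vars) {
  if (n_vars < 3) stop("edf_ratio: schedule undefined for p < 3", call. = FALSE)
  if (n_runs < 2) stop("edf_ratio: need n_runs >= 2", call. = FALSE)
  k <- log(n_vars / 2) / (n_runs - 1)
  a <- (n_vars / 2)^(1 / (n_runs - 1))
  a * exp(-k * iteration)
}

new_selection_result <- function(method, selected, scores, rmsecv_best, seed,
                                 names = NULL) {
  structure(list(method = method,
                 selected_indices = sort(unique(as.integer(selected))),
                 scores = scores, rmsecv_best = rmsecv_best, seed = seed,
                 feature_names = names),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d variable(s), best RMSECV %.4f\n",
              x$method, length(x$selected_indices), x$rmsecv_best))
  invisible(x)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte Carlo wavelength selection: each run fits PLSR on a random 80% row
#' subset, ranks variables by absolute regression coefficient, enforces the
#' exponential reduction schedule of [edf_ratio()] and then resamples the
#' survivors by adaptive reweighted sampling (weighted draws proportional to
#' coefficient magnitude, duplicates collapsed). Every run's subset is scored
#' by 5-fold RMSECV on the full sample set with a fixed fold partition; the
#' subset with the lowest RMSECV wins and is capped via [cap_selection()].
#'
#' @param X samples x variables matrix.
#' @param y response (potassium %), non-constant.
#' @param n_runs Monte Carlo runs (default 50).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed; fixes subsampling, reweighted draws and folds.
#' @param max_lv latent-variable cap inside selection.
#' @param cap maximum number of returned variables.
#' @return A `selection_result` with the RMSECV trajectory in `scores`.
#' @export
cars_select <- function(X, y, n_runs = 50, folds = 5, seed = 1L,
                        max_lv = 10, cap = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < folds) stop("cars_select: fewer samples than folds", call. = FALSE)
  if (p < 3) stop("cars_select: need >= 3 variables", call. = FALSE)
  if (sd(y) == 0) stop("cars_select: constant response", call. = FALSE)
  set.seed(seed)
  fold_id <- make_folds(n, folds)
  n_sub <- max(2L, round(0.8 * n))
  current <- seq_len(p)
  trajectory <- numeric(n_runs)
  subsets <- vector("list", n_runs)
  coefs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    rows <- sample(n, n_sub)
    lv <- max(1L, min(max_lv, length(current), n_sub - 1L))
    fit <- pls_fit_cpp(X[rows, current, drop = FALSE], y[rows], lv)
    w <- abs(fit$coef[, lv])
    # enforced reduction: keep the top ceil(r_i * p) by |coefficient|
    keep_n <- min(length(current), max(2L, ceiling(edf_ratio(i, n_runs, p) * p)))
    ord <- order(w, decreasing = TRUE)
    forced <- current[ord[seq_len(keep_n)]]
    w_forced <- w[ord[seq_len(keep_n)]]
    # adaptive reweighted sampling: weighted draws with replacement, unique
    if (all(w_forced == 0)) {
      ars <- forced
    } else {
      draws <- sample(seq_along(forced), size = keep_n, replace = TRUE,
                      prob = w_forced / sum(w_forced))
      ars <- forced[sort(unique(draws))]
    }
    if (length(ars) < 2L) ars <- forced[seq_len(min(2L, length(forced)))]
    current <- sort(ars)
    subsets[[i]] <- current
    cf <- numeric(p); cf[current] <- w_forced[match(current, forced)]
    coefs[[i]] <- cf
    trajectory[i] <- subset_rmsecv(X, y, current, fold_id, max_lv)
    if (length(current) <= 2L && i < n_runs) {
      trajectory[(i + 1):n_runs] <- trajectory[i]
      subsets[(i + 1):n_runs] <- subsets[i]
      coefs[(i + 1):n_runs] <- coefs[i]
      break
    }
  }
  best <- which.min(trajectory)
  res <- new_selection_result("CARS", subsets[[best]], trajectory,
                              trajectory[best], seed, colnames(X))
  res$best_run <- best
  res$coef_weights <- coefs[[best]]
  cap_selection(res, cap)
}

#' Random frog variable selection
#'
#' Iterative subset search: starting from a random subset of size `q0`, each
#' iteration proposes a candidate subset whose size is drawn around `q0`
#' (`round(|N(q0, 0.3 q0)|)` clipped to `[1, p]`), built by keeping a random
#' portion of the current subset and swapping in outside variables. The
#' candidate replaces the current subset if its 5-fold RMSECV is no worse,
#' and otherwise with probability `eta * (current RMSECV / candidate
#' RMSECV)`. Each variable's selection probability is the fraction of
#' iterations whose accepted subset contains it; variables at or above
#' `threshold` are returned, ranked by probability and capped.
#'
#' @param X samples x variables matrix.
#' @param y response (potassium %), non-constant.
#' @param n_iter iterations (default 10000).
#' @param threshold selection-probability cut in (0, 1); stage-specific
#'   values in the source study were 0.40, 0.21 and 0.23.
#' @param seed integer seed.
#' @param q0 nominal subset size.
#' @param eta acceptance factor for worse candidates.
#' @param folds cross-validation folds.
#' @param max_lv latent-variable cap inside selection.
#' @param cap maximum number of returned variables.
#' @return A `selection_result`; `scores` holds the per-variable selection
#'   probabilities (inclusion count / `n_iter`).
#' @export
random_frog_select <- function(X, y, n_iter = 10000, threshold = 0.40,
                               seed = 1L, q0 = 5, eta = 0.1, folds = 5,
                               max_lv = 10, cap = 10) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < folds) stop("random_frog_select: fewer samples than folds", call. = FALSE)
  if (p < 3) stop("random_frog_select: need >= 3 variables", call. = FALSE)
  if (sd(y) == 0) stop("random_frog_select: constant response", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("random_frog_select: threshold must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  fold_id <- make_folds(n, folds)
  cache <- new.env(parent = emptyenv())  # subsets recur; memoize their RMSECV
  cached_rmsecv <- function(cols) {
    key <- paste(cols, collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- subset_rmsecv(X, y, cols, fold_id, max_lv)
      cache[[key]] <- v
    }
    v
  }
  current <- sort(sample(p, min(q0, p)))
  rmse_cur <- cached_rmsecv(current)
  counts <- numeric(p)
  for (it in seq_len(n_iter)) {
    size <- round(abs(rnorm(1, q0, 0.3 * q0)))
    size <- min(max(size, 1L), p)
    if (size <= length(current)) {
      cand <- sample(current, size)
      # swap one member for an outside variable to keep the search moving
      outside <- setdiff(seq_len(p), cand)
      if (length(outside) > 0 && runif(1) < 0.5)
        cand[sample.int(length(cand), 1)] <- outside[sample.int(length(outside), 1)]
    } else {
      outside <- setdiff(seq_len(p), current)
      cand <- c(current, sample(outside, min(size - length(current),
                                             length(outside))))
    }
    cand <- sort(unique(cand))
    rmse_cand <- cached_rmsecv(cand)
    accept <- rmse_cand <= rmse_cur ||
      runif(1) < eta * (rmse_cur / rmse_cand)
    if (accept) {
      current <- cand
      rmse_cur <- rmse_cand
    }
    counts[current] <- counts[current] + 1
  }
  prob <- counts / n_iter
  names(prob) <- colnames(X)
  selected <- which(prob >= threshold)
  res <- new_selection_result("RF", selected, prob, rmse_cur, seed, colnames(X))
  cap_selection(res, cap)
}

#' Cap a selection at its best variables
#'
#' CARS results rank variables by absolute PLS coefficient in the winning
#' subset; random-frog results rank by selection probability. Ties at the
#' cap boundary resolve toward the lower variable index.
#'
#' @param result a `selection_result`.
#' @param cap maximum retained variables (>= 1).
#' @return The capped `selection_result`.
#' @export
cap_selection <- function(result, cap = 10) {
  stopifnot(cap >= 1)
  sel <- result$selected_indices
  if (length(sel) <= cap) return(result)
  score <- if (result$method == "CARS") result$coef_weights[sel]
           else result$scores[sel]
  # order: score descending, index ascending on ties
  keep <- sel[order(-score, sel)][seq_len(cap)]
  result$selected_indices <- sort(keep)
  result
}
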