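#' Concentration-gradient calibration/validation split
#'
#' Sorts samples by potassium ascending and sends the middle sample of each
#' consecutive block of three to the validation set (a 2:1 ratio), then
#' forces the global minimum and maximum into the calibration set (swapping
#' with the nearest calibration neighbour if required), so the calibration
#' set spans the full response range. 60 samples yield 40/20.
#'
#' @param k_values potassium (%) per sample, finite.
#' @param ids sample identifiers (default positional indices); must be
#'   unique.
#' @return A `split_result`: `calibration_ids`, `validation_ids`,
#'   `calibration_idx`, `validation_idx` (positions in the input order).
#' @export
concentration_gradient_split <- function(k_values, ids = seq_along(k_values)) {
  n <- length(k_values)
  if (n < 3) stop("concentration_gradient_split: need >= 3 samples", call. = FALSE)
  if (any(!is.finite(k_values)))
    stop("concentration_gradient_split: non-finite potassium values", call. = FALSE)
  if (anyDuplicated(ids))
    stop("concentration_gradient_split: duplicate sample ids", call. = FALSE)
  ord <- order(k_values)            # stable: ties keep input order
  val_pos <- integer(0)
  nblocks <- n %/% 3
  if (nblocks > 0)
    val_pos <- ord[3 * (seq_len(nblocks) - 1) + 2]  # middle of each block of 3
  # force global extremes into calibration (relevant when ties put an extreme
  # value in a middle slot)
  kmin <- which(k_values == min(k_values))
  kmax <- which(k_values == max(k_values))
  for (ext in c(kmin, kmax)) {
    hit <- which(val_pos == ext)
    if (length(hit) > 0) {
      block <- ord[pmax(1, 3 * (hit - 1) + 1):min(n, 3 * hit)]
      swap <- setdiff(block, val_pos)[1]
      val_pos[hit] <- swap
    }
  }
  cal_pos <- setdiff(seq_len(n), val_pos)
  structure(list(calibration_ids = ids[cal_pos], validation_ids = ids[val_pos],
                 calibration_idx = cal_pos, validation_idx = sort(val_pos)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d validation\n",
              length(x$calibration_ids), length(x$validation_ids)))
  invisible(x)
}

#' Fit PLSR on a split and evaluate both sets
#'
#' Fits [fit_plsr()] on the calibration rows only and reports `R2` and
#' `RMSE` on calibration and validation sets.
#'
#' @param X samples x features matrix (all samples, row-aligned with `y`).
#' @param y potassium (%) per sample.
#' @param split a [concentration_gradient_split()] result.
#' @param feature_set label for the report row.
#' @param seed fold-shuffle seed for the latent-count cross-validation.
#' @param scale unit-variance feature scaling (default TRUE here: fused
#'   tables mix units of very different magnitude).
#' @param ... further arguments to [fit_plsr()].
#' @return A `model_result`: metrics, latent count, feature count, the
#'   fitted `plsr_model`.
#' @export
fit_and_evaluate <- function(X, y, split, feature_set = "features",
                             seed = 1L, scale = TRUE, ...) {
  X <- as.matrix(X)
  cal <- split$calibration_idx; val <- split$validation_idx
  model <- fit_plsr(X[cal, , drop = FALSE], y[cal], seed = seed, scale = scale, ...)
  mc <- evaluate_metrics(y[cal], predict(model, X[cal, , drop = FALSE]))
  mv <- evaluate_metrics(y[val], predict(model, X[val, , drop = FALSE]))
  structure(list(feature_set = feature_set, n_features = ncol(X),
                 n_latent = model$n_latent,
                 r2_cal = unname(mc["r2"]), rmse_cal = unname(mc["rmse"]),
                 r2_val = unname(mv["r2"]), rmse_val = unname(mv["rmse"]),
                 model = model),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s: R2cal %.4f RMSEcal %.4f | R2val %.4f RMSEval %.4f (%d LV, %d feat)\n",
              x$feature_set, x$r2_cal, x$rmse_cal, x$r2_val, x$rmse_val,
              x$n_latent, x$n_features))
  invisible(x)
}

model_result_row <- function(stage, selector, res) {
  data.frame(stage = stage, selector = selector,
             feature_set = res$feature_set, n_features = res$n_features,
             n_latent = res$n_latent,
             r2_cal = res$r2_cal, rmse_cal = res$rmse_cal,
             r2_val = res$r2_val, rmse_val = res$rmse_val,
             stringsAsFactors = FALSE)
}

# rank rows: best = highest R2val, ties by lower RMSEval then fewer features
best_row <- function(df) {
  df[order(-df$r2_val, df$rmse_val, df$n_features), , drop = FALSE][1, ]
}

#' Compare decomposition scales, selectors and feature fusions for one stage
#'
#' The scale comparison fits PLSR on the selected characteristic wavelengths
#' of the original spectrum (`"R"`) and of every CWT scale, per selector.
#' The fusion comparison then takes the best scale row and fits the four
#' combinations spectra / +color / +texture / +color+texture, appending the
#' screened image features to the selected spectral features. Empty image
#' selections degrade the fusion row to spectra-only and are flagged.
#'
#' @param spectral_sets named list: for each selector, a named list of
#'   selected-feature matrices (samples x selected features), one per set
#'   (`"R"`, `"CWT-1"`, ...).
#' @param color,texture screened image-feature matrices (samples x features),
#'   possibly with zero columns, or NULL to skip fusion.
#' @param k_values potassium (%) per sample.
#' @param split a [concentration_gradient_split()] result.
#' @param stage stage label for the report.
#' @param seed fold-shuffle seed.
#' @return A `comparison_report`: `scale_rows`, `fusion_rows` (data.frames),
#'   `best_scale` (row), `best_combination` (row).
#' @export
fuse_and_compare <- function(spectral_sets, color = NULL, texture = NULL,
                             k_values, split, stage = "stage", seed = 1L) {
  scale_rows <- list()
  for (selector in names(spectral_sets)) {
    sets <- spectral_sets[[selector]]
    for (set_name in names(sets)) {
      X <- as.matrix(sets[[set_name]])
      if (nrow(X) != length(k_values))
        stop("fuse_and_compare: feature table rows misaligned with samples",
             call. = FALSE)
      res <- fit_and_evaluate(X, k_values, split, set_name, seed = seed)
      scale_rows[[length(scale_rows) + 1]] <-
        model_result_row(stage, selector, res)
    }
  }
  scale_rows <- do.call(rbind, scale_rows)
  cwt_rows <- scale_rows[scale_rows$feature_set != "R", , drop = FALSE]
  best_scale <- best_row(if (nrow(cwt_rows) > 0) cwt_rows else scale_rows)

  fusion_rows <- NULL; best_combination <- NULL
  if (!is.null(color) || !is.null(texture)) {
    base_name <- best_scale$feature_set
    Xbase <- as.matrix(spectral_sets[[best_scale$selector]][[base_name]])
    combos <- list()
    combos[[base_name]] <- Xbase
    add <- function(label, extra) {
      if (is.null(extra) || ncol(as.matrix(extra)) == 0) {
        # degraded: no surviving image features of this type
        attr(Xbase, "degraded") <- TRUE
        combos[[paste0(base_name, " + ", label, " [degraded to spectra-only]")]] <<- Xbase
      } else {
        combos[[paste0(base_name, " + ", label)]] <<- cbind(Xbase, as.matrix(extra))
      }
    }
    add("color", color)
    add("texture", texture)
    both <- if ((is.null(color) || ncol(as.matrix(color)) == 0) &&
                (is.null(texture) || ncol(as.matrix(texture)) == 0)) NULL
            else do.call(cbind, Filter(Negate(is.null), list(color, texture)))
    add("color + texture", both)
    fusion_rows <- do.call(rbind, lapply(names(combos), function(nm) {
      res <- fit_and_evaluate(combos[[nm]], k_values, split, nm, seed = seed)
      model_result_row(stage, best_scale$selector, res)
    }))
    best_combination <- best_row(fusion_rows)
  }
  structure(list(scale_rows = scale_rows, fusion_rows = fusion_rows,
                 best_scale = best_scale, best_combination = best_combination,
                 stage = stage),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> stage %s: %d scale rows", x$stage,
              nrow(x$scale_rows)))
  if (!is.null(x$fusion_rows))
    cat(sprintf(", %d fusion rows", nrow(x$fusion_rows)))
  cat(sprintf("\n  best scale: %s (%s) R2val %.4f\n", x$best_scale$feature_set,
              x$best_scale$selector, x$best_scale$r2_val))
  if (!is.null(x$best_combination))
    cat(sprintf("  best combination: %s R2val %.4f\n",
                x$best_combination$feature_set, x$best_combination$r2_val))
  invisible(x)
}
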