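# pixel offsets for the four GLCM directions (row, col), image row 1 at top:
# 0 deg = horizontal right, 90 deg = vertical up, 45/135 deg the diagonals
glcm_offsets <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
                     "90" = c(-1L, 0L), "135" = c(-1L, -1L))

#' Masked gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at the given direction and pixel
#' distance, keeping only pairs whose BOTH pixels lie inside the mask. The
#' matrix is symmetrized (both directions counted) and normalized to sum 1.
#' Images are taken as already quantized 8-bit (0..255); no re-binning.
#'
#' @param image integer matrix of gray levels in `0..levels-1`.
#' @param mask logical matrix, same shape; NULL means all pixels.
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @param distance pixel step (default 1).
#' @param levels number of gray levels (default 256).
#' @return `levels` x `levels` matrix with entries >= 0 summing to 1.
#' @export
glcm_matrix <- function(image, mask = NULL, angle = c(0, 45, 90, 135),
                        distance = 1L, levels = 256L) {
  angle <- match.arg(as.character(angle[1]), names(glcm_offsets))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  stopifnot(all(dim(image) == dim(mask)))
  if (any(image < 0 | image > levels - 1L, na.rm = TRUE))
    stop("glcm_matrix: gray levels outside 0..levels-1", call. = FALSE)
  off <- glcm_offsets[[angle]] * distance
  rows <- nrow(image); cols <- ncol(image)
  r1 <- seq_len(rows); c1 <- seq_len(cols)
  rs <- r1[r1 + off[1] >= 1 & r1 + off[1] <= rows]
  cs <- c1[c1 + off[2] >= 1 & c1 + off[2] <= cols]
  if (length(rs) == 0 || length(cs) == 0)
    stop("glcm_matrix: no valid pixel pairs at this offset", call. = FALSE)
  a <- image[rs, cs, drop = FALSE]
  b <- image[rs + off[1], cs + off[2], drop = FALSE]
  ok <- mask[rs, cs, drop = FALSE] & mask[rs + off[1], cs + off[2], drop = FALSE]
  if (!any(ok))
    stop("glcm_matrix: no valid masked pixel pairs at this offset", call. = FALSE)
  i <- as.integer(a[ok]); j <- as.integer(b[ok])
  counts <- tabulate(i * levels + j + 1L, nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)  # row = i, col = j
  P <- P + t(P)                                      # symmetrize
  P / sum(P)
}

#' GLCM statistics: energy, entropy, contrast, correlation
#'
#' `ENE = sum P^2`, `ENT = -sum P ln P` (with `0 ln 0 := 0`),
#' `CON = sum P (i - j)^2`, and `COR = sum P (i - MEA_i)(j - MEA_j) /
#' sqrt(VAR_i VAR_j)` where MEA/VAR are the GLCM marginal mean and variance.
#' A degenerate marginal (zero variance) yields COR = 0 with a flag.
#'
#' @param P normalized co-occurrence matrix (entries sum to 1).
#' @return Named list with `ENE`, `ENT`, `CON`, `COR`, marginal `MEA`,
#'   `VAR`, and `degenerate`.
#' @export
glcm_stats <- function(P) {
  if (abs(sum(P) - 1) > 1e-8)
    stop("glcm_stats: P must be normalized to sum 1", call. = FALSE)
  k <- nrow(P)
  lv <- seq_len(k) - 1          # gray levels 0..k-1
  ene <- sum(P^2)
  nz <- P > 0
  ent <- -sum(P[nz] * log(P[nz]))
  D <- outer(lv, lv, function(i, j) (i - j)^2)
  con <- sum(P * D)
  pi_m <- rowSums(P); pj_m <- colSums(P)
  mea_i <- sum(pi_m * lv); mea_j <- sum(pj_m * lv)
  var_i <- sum(pi_m * (lv - mea_i)^2); var_j <- sum(pj_m * (lv - mea_j)^2)
  degenerate <- var_i * var_j == 0
  cor_v <- if (degenerate) 0 else
    sum(P * outer(lv - mea_i, lv - mea_j)) / sqrt(var_i * var_j)
  list(ENE = ene, ENT = ent, CON = con, COR = cor_v,
       MEA = mea_i, VAR = var_i, degenerate = degenerate)
}

#' The 24 texture features of one characteristic-wavelength grayscale image
#'
#' ENE/ENT/CON/COR at the four directions (16 features) plus the mean and
#' variance of each statistic across directions (8 features), named
#' `"<nm> nm-<STAT>-<angle>"` and `"<nm> nm-MEA (<STAT>)"` /
#' `"<nm> nm-VAR (<STAT>)"`. Across-direction variance is the population
#' form (divide by 4).
#'
#' @param image integer 8-bit grayscale matrix.
#' @param mask logical matrix; pairs must have both pixels masked.
#' @param wavelength_nm wavelength used in the feature names.
#' @param distance,levels GLCM settings (see [glcm_matrix()]).
#' @return Named numeric vector of length 24.
#' @export
texture_features <- function(image, mask = NULL, wavelength_nm = NA,
                             distance = 1L, levels = 256L) {
  stats_by_angle <- lapply(names(glcm_offsets), function(ang) {
    P <- glcm_matrix(image, mask, as.numeric(ang), distance, levels)
    glcm_stats(P)
  })
  names(stats_by_angle) <- names(glcm_offsets)
  stat_names <- c("ENE", "ENT", "CON", "COR")
  lab <- if (is.na(wavelength_nm)) "" else sprintf("%g nm-", wavelength_nm)
  out <- numeric(0)
  for (st in stat_names)
    for (ang in names(glcm_offsets)) {
      v <- stats_by_angle[[ang]][[st]]
      names(v) <- sprintf("%s%s-%s°", lab, st, ang)
      out <- c(out, v)
    }
  for (st in stat_names) {
    vals <- vapply(stats_by_angle, function(s) s[[st]], numeric(1))
    m <- mean(vals); v <- mean((vals - m)^2)
    names(m) <- sprintf("%sMEA (%s)", lab, st)
    names(v) <- sprintf("%sVAR (%s)", lab, st)
    out <- c(out, m, v)
  }
  out
}

#' Color moments of a masked grayscale image
#'
#' First moment `MEA` (mean gray level), second moment `VAR` (root mean
#' squared deviation) and third moment `SKE` (signed cube root of the third
#' central moment), over masked pixels of the single gray channel.
#'
#' @param image numeric or integer matrix of gray levels.
#' @param mask logical matrix; NULL means all pixels.
#' @param wavelength_nm wavelength used in the feature names.
#' @return Named numeric `c(MEA, VAR, SKE)` in gray-level units.
#' @export
color_moments <- function(image, mask = NULL, wavelength_nm = NA) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  px <- as.numeric(image[mask])
  if (length(px) == 0) stop("color_moments: empty mask", call. = FALSE)
  mea <- mean(px)
  v2 <- mean((px - mea)^2)
  v3 <- mean((px - mea)^3)
  ske <- sign(v3) * abs(v3)^(1 / 3)
  out <- c(mea, sqrt(v2), ske)
  lab <- if (is.na(wavelength_nm)) "" else sprintf("%g nm-", wavelength_nm)
  names(out) <- paste0(lab, c("MEA", "VAR", "SKE"))
  out
}

#' Screen image features by correlation then CARS
#'
#' Stage 1 keeps features whose Pearson correlation with potassium is
#' significant at `p_cut`; stage 2 runs [cars_select()] on the survivors.
#' With no survivors an empty selection is returned with a warning and the
#' downstream fusion degrades to spectra-only.
#'
#' @param table samples x features matrix with feature names as columns.
#' @param k_values potassium (%) per sample.
#' @param seed seed passed to CARS.
#' @param p_cut stage-1 significance level.
#' @param cap maximum retained features.
#' @param ... further arguments to [cars_select()].
#' @return A `selection_result` whose `selected_indices` index into `table`
#'   columns; `selected_names` carries the feature names.
#' @export
screen_image_features <- function(table, k_values, seed = 1L, p_cut = 0.05,
                                  cap = 10, ...) {
  table <- as.matrix(table)
  if (nrow(table) < 3)
    stop("screen_image_features: need >= 3 samples", call. = FALSE)
  pvals <- apply(table, 2, function(col) {
    if (sd(col) == 0) return(1)
    cor.test(col, k_values)$p.value
  })
  survivors <- which(pvals < p_cut)
  if (length(survivors) == 0) {
    warning("screen_image_features: no feature passed the correlation screen; ",
            "returning empty selection")
    res <- new_selection_result("CARS", integer(0), pvals, NA_real_, seed,
                                colnames(table))
    res$selected_names <- character(0)
    return(res)
  }
  if (length(survivors) < 3) {
    # too few for CARS; keep the survivors directly
    res <- new_selection_result("CARS", survivors, pvals, NA_real_, seed,
                                colnames(table))
    res$selected_names <- colnames(table)[res$selected_indices]
    return(res)
  }
  inner <- cars_select(table[, survivors, drop = FALSE], k_values,
                       seed = seed, cap = cap, ...)
  res <- inner
  res$selected_indices <- survivors[inner$selected_indices]
  res$feature_names <- colnames(table)
  res$selected_names <- colnames(table)[res$selected_indices]
  res
}
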