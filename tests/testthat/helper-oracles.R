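# Independent oracles and small fixtures shared across the test files.
# Oracles are deliberately naive (explicit loops, textbook formulas) and do
# not reuse the package's vectorised code paths.

# small scene config used throughout the tests
test_scene <- function(...) {
  scene_config(image_shape = c(64L, 64L), ...)
}

# noiseless variant: every stochastic or K-independent term switched off
noiseless_scene <- function(...) {
  scene_config(image_shape = c(64L, 64L), noise_sd = 0, field_amplitude = 0,
               bio_plateau_sd = 0, bio_gain_sd = 0, bio_green_sd = 0,
               bio_rededge_sd_nm = 0, ...)
}

# brute-force CWT: pointwise wavelet evaluation with its own mirror folding
oracle_cwt <- function(f, scale_exponent) {
  n <- length(f)
  a <- 2^scale_exponent
  half <- ceiling(1.5 * a)
  psi <- leafspec:::sym2_psi
  fold <- function(i) {
    m <- (i - 1) %% (2 * n)
    ifelse(m < n, m + 1, 2 * n - m)
  }
  vapply(seq_len(n), function(b) {
    lam <- seq(b - half, b + half)
    sum(f[fold(lam)] * psi((lam - b) / a) / sqrt(a))
  }, numeric(1))
}

# brute-force masked GLCM by explicit pair enumeration
oracle_glcm <- function(image, mask, angle, distance = 1L, levels = 256L) {
  offs <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
               "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  off <- offs[[as.character(angle)]] * distance
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(image)))
    for (c in seq_len(ncol(image))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(image) && c2 >= 1 && c2 <= ncol(image) &&
          mask[r, c] && mask[r2, c2]) {
        i <- image[r, c] + 1L; j <- image[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1
        P[j, i] <- P[j, i] + 1    # symmetrization
      }
    }
  if (sum(P) == 0) stop("oracle_glcm: no pairs")
  P / sum(P)
}

# double-loop GLCM statistics from the textbook formulas
oracle_glcm_stats <- function(P) {
  k <- nrow(P)
  ene <- 0; ent <- 0; con <- 0
  mea_i <- 0; mea_j <- 0
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      p <- P[i, j]
      ene <- ene + p^2
      if (p > 0) ent <- ent - p * log(p)
      con <- con + p * ((i - 1) - (j - 1))^2
      mea_i <- mea_i + p * (i - 1)
      mea_j <- mea_j + p * (j - 1)
    }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      p <- P[i, j]
      var_i <- var_i + p * ((i - 1) - mea_i)^2
      var_j <- var_j + p * ((j - 1) - mea_j)^2
      cov_ij <- cov_ij + p * ((i - 1) - mea_i) * ((j - 1) - mea_j)
    }
  cor_v <- if (var_i * var_j == 0) 0 else cov_ij / sqrt(var_i * var_j)
  list(ENE = ene, ENT = ent, CON = con, COR = cor_v, MEA = mea_i, VAR = var_i)
}

# pure-R NIPALS PLS1: independent of the compiled SIMPLS path
oracle_nipals_pls <- function(X, y, ncomp) {
  X0 <- scale(X, scale = FALSE)
  y0 <- y - mean(y)
  xm <- attr(X0, "scaled:center")
  W <- NULL; P <- NULL; Q <- NULL
  E <- X0; f <- y0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w^2))
    t <- drop(E %*% w); tt <- sum(t^2)
    p <- drop(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, p)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  B <- W %*% solve(crossprod(P, W), Q)
  list(coef = drop(B), x_means = xm, y_mean = mean(y),
       predict = function(Xn) mean(y) + drop(sweep(Xn, 2, xm) %*% B))
}

# random masked test image with all four offsets guaranteed some pairs
random_masked_image <- function(rows, cols, levels = 16L) {
  img <- matrix(sample.int(levels, rows * cols, replace = TRUE) - 1L, rows, cols)
  mask <- matrix(runif(rows * cols) > 0.3, rows, cols)
  # ensure a solid 3x3 block so every direction has valid pairs
  mask[1:3, 1:3] <- TRUE
  list(image = img, mask = mask)
}
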