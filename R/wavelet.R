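# --- sym2 mother wavelet ---------------------------------------------------
#
# sym2 reconstruction filters (identical to Daubechies-2). The wavelet
# function is sampled by cascade refinement: start from the highpass filter
# and repeatedly upsample-and-convolve with the lowpass; after L levels the
# values approximate psi on a grid of spacing 2^-L over its support [0, 3].
sym2_filters <- function() {
  s3 <- sqrt(3)
  rec_lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  rec_hi <- c(rec_lo[4], -rec_lo[3], rec_lo[2], -rec_lo[1])
  list(lo = rec_lo, hi = rec_hi)
}

# cache of cascade samples: value k corresponds to psi((k) / 2^level) with
# support [0, 3]; sampled at >= 2^10 points per the documented scheme
sym2_cache <- new.env(parent = emptyenv())

sym2_samples <- function(level = 12L) {
  key <- as.character(level)
  if (!is.null(sym2_cache[[key]])) return(sym2_cache[[key]])
  f <- sym2_filters()
  p <- f$hi * sqrt(2)
  for (i in seq_len(level - 1L)) {
    up <- numeric(2L * length(p) - 1L)
    up[seq(1L, length(up), by = 2L)] <- p
    p <- convolve(up, rev(f$lo * sqrt(2)), type = "open")
  }
  # sample k (1-based) sits at x = k / 2^level
  out <- list(values = p, dx = 2^(-level), support = c(0, 3))
  sym2_cache[[key]] <- out
  out
}

# evaluate the CENTERED mother wavelet psi_c(t) = psi(t + 1.5) by linear
# interpolation of the cascade samples; zero outside [-1.5, 1.5]
sym2_psi <- function(t, level = 12L) {
  s <- sym2_samples(level)
  x <- t + 1.5
  out <- numeric(length(t))
  inside <- x > 0 & x < 3
  if (any(inside)) {
    pos <- x[inside] / s$dx            # 1-based fractional sample index
    k0 <- floor(pos)
    frac <- pos - k0
    v <- s$values
    left <- ifelse(k0 >= 1 & k0 <= length(v), v[pmax(k0, 1)], 0)
    right <- ifelse(k0 + 1 >= 1 & k0 + 1 <= length(v), v[pmin(k0 + 1, length(v))], 0)
    left[k0 < 1] <- 0
    right[k0 + 1 > length(v)] <- 0
    out[inside] <- (1 - frac) * left + frac * right
  }
  out
}

# discrete correlation kernel for scale a: w(t) = psi_c(t / a) / sqrt(a),
# t integer in [-ceil(1.5 a), ceil(1.5 a)]
cwt_kernel <- function(a, level = 12L) {
  half <- ceiling(1.5 * a)
  t <- seq(-half, half)
  list(t = t, w = sym2_psi(t / a, level) / sqrt(a), half = half)
}

# half-sample symmetric (mirror, edge duplicated) index folding into 1..n
fold_index <- function(i, n) {
  m <- (i - 1L) %% (2L * n)
  m[m < 0L] <- m[m < 0L] + 2L * n
  ifelse(m < n, m + 1L, 2L * n - m)
}

#' Continuous wavelet transform of a spectrum at dyadic scales
#'
#' Computes `W(a, b) = sum_lambda f(lambda) psi_ab(lambda)` along the band
#' index (unit spacing) with the sym2 mother wavelet centered at `b`, scale
#' `a = 2^i`, normalization `1/sqrt(a)`, and half-sample symmetric boundary
#' extension. Rows of the result are scales (`CWT-i`), columns are bands, the
#' "m by n" coefficient matrix layout of multi-scale spectral decomposition.
#'
#' @param spectrum numeric reflectance per band (length >= 4).
#' @param scale_exponents integer scale exponents `i` with `a = 2^i`,
#'   a subset of 1..10.
#' @param grid optional [band_grid()] carried into the result.
#' @return A `wavelet_coefficients` object: `coefficients` (m scales x n
#'   bands), `scales` (the exponents), `grid`.
#' @export
cwt_spectrum <- function(spectrum, scale_exponents = 1:10, grid = NULL) {
  n <- length(spectrum)
  if (n < 4) stop("cwt_spectrum: spectrum shorter than the wavelet support",
                  call. = FALSE)
  if (!all(scale_exponents %in% 1:10))
    stop("cwt_spectrum: scale exponents must lie in 1..10", call. = FALSE)
  W <- matrix(NA_real_, length(scale_exponents), n)
  for (si in seq_along(scale_exponents)) {
    k <- cwt_kernel(2^scale_exponents[si])
    ext <- spectrum[fold_index(seq(1L - k$half, n + k$half), n)]
    for (b in seq_len(n))
      W[si, b] <- sum(ext[(b - 1L) + seq_along(k$w)] * k$w)
  }
  rownames(W) <- sprintf("CWT-%d", scale_exponents)
  if (!is.null(grid)) colnames(W) <- sprintf("%.1fnm", as.numeric(grid))
  structure(list(coefficients = W, scales = scale_exponents, grid = grid),
            class = "wavelet_coefficients")
}

#' CWT coefficient stack for a spectra matrix
#'
#' Applies the transform of [cwt_spectrum()] to each row of a samples x bands
#' matrix and returns, per scale, a samples x bands coefficient matrix. The
#' whole stack is computed as one matrix product per scale (mirror-extended
#' spectra times a kernel placement matrix), numerically identical to the
#' per-spectrum path.
#'
#' @param spectra samples x bands matrix.
#' @param scale_exponents scale exponents (see [cwt_spectrum()]).
#' @param grid optional [band_grid()].
#' @return Named list (`"CWT-1"`, ...) of samples x bands matrices.
#' @export
cwt_stack <- function(spectra, scale_exponents = 1:10, grid = NULL) {
  n <- ncol(spectra)
  out <- lapply(scale_exponents, function(i) {
    k <- cwt_kernel(2^i)
    ext_idx <- fold_index(seq(1L - k$half, n + k$half), n)
    ext <- spectra[, ext_idx, drop = FALSE]
    L <- length(k$w)
    placement <- matrix(0, length(ext_idx), n)
    for (b in seq_len(n)) placement[(b - 1L) + seq_len(L), b] <- k$w
    m <- ext %*% placement
    rownames(m) <- rownames(spectra)
    if (!is.null(grid)) colnames(m) <- sprintf("%.1fnm", as.numeric(grid))
    m
  })
  names(out) <- sprintf("CWT-%d", scale_exponents)
  out
}

#' Scale-by-wavelength correlation map against potassium
#'
#' For each decomposition scale and band, the absolute Pearson correlation
#' across samples between the wavelet coefficients and leaf potassium.
#' Zero-variance coefficient columns yield 0 and are flagged.
#'
#' @param coeff_stack a [cwt_stack()] result (list of samples x bands
#'   matrices).
#' @param k_values potassium (%) per sample, non-degenerate.
#' @return A `correlation_map`: `abs_r` (scales x bands in `[0, 1]`),
#'   `per_scale_max`, `n` (sample count), `degenerate` (logical matrix).
#' @export
correlation_map <- function(coeff_stack, k_values) {
  n <- length(k_values)
  if (n < 3) stop("correlation_map: need >= 3 samples", call. = FALSE)
  if (sd(k_values) == 0)
    stop("correlation_map: potassium values are constant", call. = FALSE)
  abs_r <- t(vapply(coeff_stack, function(M) {
    sds <- apply(M, 2, sd)
    r <- rep(0, ncol(M))
    ok <- sds > 0
    r[ok] <- abs(as.numeric(cor(M[, ok, drop = FALSE], k_values)))
    r
  }, numeric(ncol(coeff_stack[[1]]))))
  rownames(abs_r) <- names(coeff_stack)
  colnames(abs_r) <- colnames(coeff_stack[[1]])
  degen <- t(vapply(coeff_stack, function(M) apply(M, 2, sd) == 0,
                    logical(ncol(coeff_stack[[1]]))))
  structure(list(abs_r = abs_r, per_scale_max = apply(abs_r, 1, max),
                 n = n, degenerate = degen),
            class = "correlation_map")
}

#' Wavelet-coefficient grayscale image at one scale and wavelength
#'
#' Computes the per-pixel CWT along the spectral axis at scale `2^i`, takes
#' the coefficient at the band nearest `wavelength`, min-max scales it to
#' 0..255 over the masked pixels and zeroes the background. Because of the
#' per-image min-max, a global illumination gain leaves the image unchanged.
#'
#' @param cube a reflectance [hypercube()] (already trimmed to the working
#'   window).
#' @param mask logical leaf mask.
#' @param scale_exponent scale exponent `i` (`a = 2^i`).
#' @param wavelength nm; nearest band center is used.
#' @param raw_band if TRUE, skip the CWT and scale the raw band image
#'   instead (alternative grayscale-database mode).
#' @return Integer matrix 0..255, background 0.
#' @export
coefficient_image <- function(cube, mask, scale_exponent, wavelength,
                              raw_band = FALSE) {
  d <- dim(cube$values)
  b0 <- nearest_band(cube$grid, wavelength)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  px <- which(mask)
  if (raw_band) {
    coef <- flat[px, b0]
  } else {
    k <- cwt_kernel(2^scale_exponent)
    idx <- fold_index(b0 + k$t, d[3])
    coef <- as.numeric(flat[px, idx, drop = FALSE] %*% k$w)
  }
  img <- matrix(0L, d[1], d[2])
  rng <- range(coef)
  if (rng[2] - rng[1] <= 0) {
    warning("coefficient_image: constant coefficient field over mask; ",
            "returning all-zero image")
    return(img)
  }
  img[px] <- as.integer(round((coef - rng[1]) / (rng[2] - rng[1]) * 255))
  img
}
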