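#' Scene configuration for the synthetic leaf-scene generator
#'
#' Defaults emulate the study conditions the pipeline assumes: a 128-band
#' 376--1044 nm sensor grid, three cotton growth stages with 60 leaves each,
#' stage potassium distributions with the published min/max/mean/sd, a dark
#' background plate well below the 0.25 segmentation threshold and a gray
#' reference panel well above it. The desk-scale default image is 192 x 192
#' pixels; the full 692 x 520 acquisition frame is available by config.
#'
#' @param image_shape integer (rows, cols) of the scene.
#' @param n_leaves_per_stage leaves generated per growth stage.
#' @param stage_k_params named list per stage of `c(min, max, mean, sd)` in %
#'   potassium of dry mass.
#' @param panel_reflectance gray reference panel reflectance in (0, 1].
#' @param background_reflectance background plate reflectance (< 0.25).
#' @param noise_sd additive Gaussian sensor noise, DN.
#' @param illumination_gain DN per unit reflectance.
#' @param dark_current DN offset.
#' @param field_amplitude amplitude of the smooth multiplicative spatial field
#'   over the leaf (venation/illumination proxy), unitless.
#' @param bio_plateau_sd,bio_gain_sd,bio_green_sd,bio_rededge_sd_nm per-leaf
#'   biological variability independent of potassium: additive NIR-plateau
#'   jitter (reflectance), multiplicative whole-leaf gain jitter (relative),
#'   green-peak amplitude jitter (relative) and red-edge inflection jitter
#'   (nm). These set how far below 1 the spectra-only estimation ceiling
#'   sits, as in real campaigns; zero them for noiseless recovery tests.
#' @param grid sensor [band_grid()].
#' @param truth a [ground_truth_params()] bundle of K-effect link strengths.
#' @return A `scene_config` list, validated.
#' @export
scene_config <- function(image_shape = c(192L, 192L),
                         n_leaves_per_stage = 60L,
                         stage_k_params = list(
                           budding   = c(min = 0.51, max = 3.56, mean = 1.63, sd = 0.81),
                           flowering = c(min = 0.57, max = 2.80, mean = 1.18, sd = 0.44),
                           boll      = c(min = 0.40, max = 2.30, mean = 1.25, sd = 0.56)),
                         panel_reflectance = 0.60,
                         background_reflectance = 0.05,
                         noise_sd = 8,
                         illumination_gain = 4000,
                         dark_current = 100,
                         field_amplitude = 0.05,
                         bio_plateau_sd = 0.03,
                         bio_gain_sd = 0.03,
                         bio_green_sd = 0.10,
                         bio_rededge_sd_nm = 3,
                         grid = band_grid(),
                         truth = ground_truth_params()) {
  for (s in names(stage_k_params)) {
    p <- stage_k_params[[s]]
    if (!(p["min"] < p["mean"] && p["mean"] < p["max"]))
      stop("scene_config: stage '", s, "' needs min < mean < max", call. = FALSE)
  }
  if (panel_reflectance <= 0.25 || panel_reflectance > 1)
    stop("scene_config: panel_reflectance must lie in (0.25, 1]", call. = FALSE)
  if (background_reflectance >= 0.25)
    stop("scene_config: background_reflectance must be < 0.25", call. = FALSE)
  if (noise_sd < 0 || illumination_gain <= 0 || dark_current < 0)
    stop("scene_config: invalid sensor parameters", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape),
                 n_leaves_per_stage = as.integer(n_leaves_per_stage),
                 stage_k_params = stage_k_params,
                 panel_reflectance = panel_reflectance,
                 background_reflectance = background_reflectance,
                 noise_sd = noise_sd,
                 illumination_gain = illumination_gain,
                 dark_current = dark_current,
                 field_amplitude = field_amplitude,
                 bio_plateau_sd = bio_plateau_sd,
                 bio_gain_sd = bio_gain_sd,
                 bio_green_sd = bio_green_sd,
                 bio_rededge_sd_nm = bio_rededge_sd_nm,
                 grid = grid, truth = truth),
            class = "scene_config")
}

#' Ground-truth K-effect link strengths
#'
#' The generator couples leaf potassium to the scene through three linear
#' links: the NIR plateau height falls with K (`nir_slope`, reflectance per %
#' K), the speckle amplitude falls with K (`texture_effect`, peak relative
#' amplitude at the low end of `k_range`), and overall brightness falls with K
#' (`color_effect`, relative gain per % K around the range midpoint).
#'
#' @param k_range admissible K range (%), wide enough for all stages.
#' @param nir_slope reflectance decrease of the NIR plateau per % K.
#' @param texture_effect maximum relative speckle amplitude (at minimum K).
#' @param color_effect relative brightness change per % K below the midpoint.
#' @param informative_region nm window where the K-spectral link acts.
#' @return A `ground_truth_params` list.
#' @export
ground_truth_params <- function(k_range = c(0.30, 3.80),
                                nir_slope = 0.06,
                                texture_effect = 0.05,
                                color_effect = 0.02,
                                informative_region = c(760, 950)) {
  structure(list(k_range = k_range, nir_slope = nir_slope,
                 texture_effect = texture_effect, color_effect = color_effect,
                 informative_region = informative_region),
            class = "ground_truth_params")
}

#' Green-leaf reflectance model with a linear potassium link
#'
#' Builds a smooth reflectance spectrum with the canonical green-vegetation
#' shape: chlorophyll absorption minima near 450 and 680 nm, the green
#' reflection maximum near 550 nm, the red-edge rise over 690--760 nm and a
#' NIR plateau over 760--950 nm. Potassium couples linearly to the plateau
#' height with negative slope, so K-deficient leaves are brighter in the NIR.
#'
#' @param k_percent leaf potassium, % of dry mass; must lie in
#'   `truth$k_range`.
#' @param grid [band_grid()] of band centers (nm).
#' @param truth [ground_truth_params()].
#' @param bio optional per-leaf biological perturbation, a list with
#'   `plateau_delta` (reflectance), `green_mult` (relative) and
#'   `rededge_nm` (inflection shift, nm); all zero/one when NULL.
#' @return Numeric reflectance per band, in `[0, 1.2]`.
#' @export
reflectance_model <- function(k_percent, grid, truth = ground_truth_params(),
                              bio = NULL) {
  if (k_percent < truth$k_range[1] || k_percent > truth$k_range[2])
    stop("reflectance_model: k_percent ", k_percent, " outside configured range [",
         truth$k_range[1], ", ", truth$k_range[2], "]", call. = FALSE)
  if (is.null(bio)) bio <- list(plateau_delta = 0, green_mult = 1, rededge_nm = 0)
  nm <- as.numeric(grid)
  k_mid <- mean(truth$k_range)
  base <- 0.08
  green_peak <- 0.13 * bio$green_mult * exp(-((nm - 550) / 28)^2)
  blue_dip <- -0.02 * exp(-((nm - 450) / 20)^2)
  red_dip <- -0.02 * exp(-((nm - 680) / 18)^2)
  plateau <- 0.45 + truth$nir_slope * (k_mid - k_percent) + bio$plateau_delta
  red_edge <- plateau * stats::plogis((nm - (715 + bio$rededge_nm)) / 12)
  r <- base + green_peak + blue_dip + red_dip + red_edge
  pmin(pmax(r, 0), 1.2)
}

# per-leaf speckle amplitude: linear in K, maximal at the low end of the range
speckle_amplitude <- function(k_percent, truth) {
  kr <- truth$k_range
  truth$texture_effect * (kr[2] - k_percent) / (kr[2] - kr[1])
}

# per-leaf brightness gain: linear in K around the range midpoint
brightness_gain <- function(k_percent, truth) {
  1 + truth$color_effect * (mean(truth$k_range) - k_percent)
}

# randomized 5-lobed polar leaf shape rasterized onto the pixel grid;
# non-convex by construction so masked texture extraction is exercised
leaf_shape_mask <- function(rows, cols, lobe_phase, harm_phase) {
  cy <- rows * 0.45; cx <- cols * 0.5
  r0 <- 0.30 * min(rows, cols)
  y <- matrix(seq_len(rows), rows, cols) - cy
  x <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cx
  theta <- atan2(y, x)
  rad <- sqrt(x^2 + y^2)
  rim <- r0 * (1 + 0.25 * cos(5 * theta + lobe_phase) +
                 0.06 * cos(2 * theta + harm_phase))
  rad <= rim
}

# smooth low-frequency multiplicative field (venation / illumination proxy)
smooth_field <- function(rows, cols, amplitude, phases) {
  y <- matrix(seq_len(rows) / rows, rows, cols)
  x <- matrix(seq_len(cols) / cols, rows, cols, byrow = TRUE)
  f <- cos(2 * pi * (1.3 * x + 0.9 * y) + phases[1]) +
    0.7 * cos(2 * pi * (2.1 * x - 1.7 * y) + phases[2]) +
    0.5 * cos(2 * pi * (3.0 * y) + phases[3])
  1 + amplitude * f / 2.2
}

#' Render one synthetic leaf scene as a raw-DN hypercube
#'
#' The scene holds a lobed leaf on a dark background plate with a gray
#' reference panel strip along the top edge. Per-pixel leaf spectra are
#' `reflectance_model(k)` scaled by a smooth spatial field and a K-dependent
#' speckle term; DN counts are `reflectance * gain + dark_current +
#' N(0, noise_sd)`. Identical `(config, k_percent, seed)` give bit-identical
#' cubes.
#'
#' @param config a [scene_config()].
#' @param k_percent leaf potassium, %.
#' @param seed integer seed for this scene.
#' @return List with `cube` (DN [hypercube()] carrying panel/background
#'   regions) and `leaf_mask` (logical ground-truth mask).
#' @export
render_scene <- function(config, k_percent, seed) {
  set.seed(seed)
  rows <- config$image_shape[1]; cols <- config$image_shape[2]
  truth <- config$truth
  n_bands <- length(config$grid)

  panel <- matrix(FALSE, rows, cols)
  panel[seq_len(max(2L, round(rows * 0.08))), ] <- TRUE

  mask <- leaf_shape_mask(rows, cols, runif(1, 0, 2 * pi), runif(1, 0, 2 * pi))
  mask[panel] <- FALSE
  if (!any(mask))
    stop("render_scene: leaf region empty after shape synthesis", call. = FALSE)

  bio <- list(plateau_delta = rnorm(1, 0, config$bio_plateau_sd),
              green_mult = max(0.2, rnorm(1, 1, config$bio_green_sd)),
              rededge_nm = rnorm(1, 0, config$bio_rededge_sd_nm))
  leaf_gain <- max(0.5, rnorm(1, 1, config$bio_gain_sd))
  spectrum <- reflectance_model(k_percent, config$grid, truth, bio)
  field <- smooth_field(rows, cols, config$field_amplitude,
                        runif(3, 0, 2 * pi))
  amp <- speckle_amplitude(k_percent, truth)
  speckle <- 1 + amp * matrix(rnorm(rows * cols), rows, cols)
  gain_px <- leaf_gain * brightness_gain(k_percent, truth) * field * speckle

  refl <- array(config$background_reflectance, c(rows, cols, n_bands))
  leaf_idx <- which(mask)
  panel_idx <- which(panel)
  plane <- rows * cols
  for (b in seq_len(n_bands)) {
    off <- (b - 1) * plane
    refl[off + leaf_idx] <- pmin(pmax(spectrum[b] * gain_px[leaf_idx], 0), 1.2)
    refl[off + panel_idx] <- config$panel_reflectance
  }

  dn <- refl * config$illumination_gain + config$dark_current
  if (config$noise_sd > 0)
    dn <- dn + array(rnorm(length(dn), 0, config$noise_sd), dim(dn))
  dn[dn < 0] <- 0

  cube <- hypercube(dn, config$grid, units = "dn",
                    panel_region = panel, background_region = !panel & !mask)
  list(cube = cube, leaf_mask = mask)
}

# truncated-normal moments on [a, b] for N(mu, sigma)
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  dm <- (dnorm(al) - dnorm(be)) / Z
  m <- mu + sigma * dm
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - dm^2)
  c(mean = unname(m), sd = unname(sqrt(v)))
}

# solve for (mu, sigma) of the parent normal so that the TRUNCATED
# distribution on [min, max] reproduces the target mean and sd jointly.
# sigma is capped at twice the range width: beyond that the truncated shape
# is already at its uniform limit (no sd gain) while rejection sampling
# degenerates. Targets beyond the family's sd ceiling get the closest match.
match_truncnorm <- function(target_mean, target_sd, a, b) {
  target_mean <- unname(target_mean); target_sd <- unname(target_sd)
  a <- unname(a); b <- unname(b)
  sigma_cap <- 2 * (b - a)
  obj <- function(par) {
    sigma <- min(exp(par[2]), sigma_cap)
    m <- truncnorm_moments(par[1], sigma, a, b)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = min(exp(fit$par[2]), sigma_cap))
}

# rejection sampler for the truncated normal
rtruncnorm_reject <- function(n, mu, sigma, a, b) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * n, mu, sigma)
    out <- c(out, x[x >= a & x <= b])
  }
  out[seq_len(n)]
}

#' Generate a seeded multi-stage leaf campaign
#'
#' Draws per-leaf potassium from a truncated normal on each stage's
#' `[min, max]` whose parent parameters are moment-matched so the truncated
#' distribution reproduces the stage mean and sd, then assigns each leaf a
#' derived scene seed. Cubes are rendered lazily through `$render(i)` so a
#' default 180-leaf campaign does not hold 180 cubes in memory; pass
#' `keep_cubes = TRUE` (small scenes) to materialize them.
#'
#' @param config a [scene_config()].
#' @param seed campaign seed; all K draws and scene seeds derive from it.
#' @param stages which stages of `config$stage_k_params` to generate.
#' @param keep_cubes materialize all cubes in the returned object.
#' @return A `campaign` list: `samples` (data.frame with sample_id, stage,
#'   k_percent, scene_seed), `render(i)` closure returning
#'   [render_scene()] output for row `i`, `config`, and optionally `cubes`.
#' @export
generate_campaign <- function(config = scene_config(), seed = 1L,
                              stages = names(config$stage_k_params),
                              keep_cubes = FALSE) {
  if (config$n_leaves_per_stage < 3)
    stop("generate_campaign: need >= 3 leaves per stage for a 2:1 split",
         call. = FALSE)
  rows <- list()
  for (si in seq_along(stages)) {
    s <- stages[si]
    p <- config$stage_k_params[[s]]
    par <- match_truncnorm(p["mean"], p["sd"], p["min"], p["max"])
    set.seed(sub_seed(seed, si))
    k <- rtruncnorm_reject(config$n_leaves_per_stage, par["mu"], par["sigma"],
                           p["min"], p["max"])
    rows[[si]] <- data.frame(
      sample_id = sprintf("%s_%03d", s, seq_len(config$n_leaves_per_stage)),
      stage = s, k_percent = k,
      scene_seed = sub_seed(seed, 1000L * si + seq_len(config$n_leaves_per_stage)),
      stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  render <- function(i) {
    render_scene(config, samples$k_percent[i], samples$scene_seed[i])
  }
  out <- structure(list(samples = samples, render = render, config = config),
                   class = "campaign")
  if (keep_cubes) {
    out$cubes <- lapply(seq_len(nrow(samples)), render)
    cubes <- out$cubes
    out$render <- function(i) cubes[[i]]
  }
  out
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign> %d samples over %d stage(s); cubes %s\n",
              nrow(x$samples), length(unique(x$samples$stage)),
              if (is.null(x$cubes)) "rendered lazily via $render(i)" else "materialized"))
  invisible(x)
}
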