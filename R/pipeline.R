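#' Run configuration for the end-to-end pipeline
#'
#' Bundles the scene generator settings with every analysis default: dyadic
#' scales 1--10, both selectors, CARS with 50 Monte Carlo runs and 5-fold
#' cross-validation, random frog with 10,000 iterations and stage selection
#' thresholds 0.40 / 0.21 / 0.23, GLCM with 256 gray levels, step 1 and four
#' directions, a 2:1 concentration-gradient split and a 10-wavelength cap.
#'
#' @param scene a [scene_config()].
#' @param stages stages to run (subset of the scene's stage names).
#' @param scales CWT scale exponents.
#' @param selectors `"cars"`, `"rf"` or both.
#' @param rf_thresholds named (or positional) per-stage random-frog
#'   selection-probability thresholds.
#' @param cars_runs,cv_folds CARS Monte Carlo runs and CV folds.
#' @param rf_iterations random-frog iterations.
#' @param cap characteristic-wavelength cap.
#' @param glcm_levels,glcm_distance GLCM settings.
#' @param seed master seed; per-stage sub-seeds derive from it.
#' @param with_images compute image features and fusion rows (slower).
#' @return A `run_config` list.
#' @export
run_config <- function(scene = scene_config(),
                       stages = names(scene$stage_k_params),
                       scales = 1:10,
                       selectors = c("cars", "rf"),
                       rf_thresholds = c(budding = 0.40, flowering = 0.21,
                                         boll = 0.23),
                       cars_runs = 50, cv_folds = 5, rf_iterations = 10000,
                       cap = 10, glcm_levels = 256L, glcm_distance = 1L,
                       seed = 1L, with_images = TRUE) {
  selectors <- match.arg(selectors, c("cars", "rf"), several.ok = TRUE)
  structure(list(scene = scene, stages = stages, scales = scales,
                 selectors = selectors, rf_thresholds = rf_thresholds,
                 cars_runs = cars_runs, cv_folds = cv_folds,
                 rf_iterations = rf_iterations, cap = cap,
                 glcm_levels = glcm_levels, glcm_distance = glcm_distance,
                 seed = seed, with_images = with_images),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`;
#'   `write_run_config` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sc_args <- y$scene %||% list()
  if (!is.null(sc_args$stage_k_params))
    sc_args$stage_k_params <- lapply(sc_args$stage_k_params, unlist)
  if (!is.null(sc_args$truth))
    sc_args$truth <- do.call(ground_truth_params, sc_args$truth)
  scene <- do.call(scene_config, sc_args)
  args <- y[setdiff(names(y), "scene")]
  if (!is.null(args$rf_thresholds)) args$rf_thresholds <- unlist(args$rf_thresholds)
  do.call(run_config, c(list(scene = scene), args))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  scene <- config$scene
  y <- list(
    scene = list(image_shape = scene$image_shape,
                 n_leaves_per_stage = scene$n_leaves_per_stage,
                 stage_k_params = lapply(scene$stage_k_params, as.list),
                 panel_reflectance = scene$panel_reflectance,
                 background_reflectance = scene$background_reflectance,
                 noise_sd = scene$noise_sd,
                 illumination_gain = scene$illumination_gain,
                 dark_current = scene$dark_current,
                 field_amplitude = scene$field_amplitude,
                 bio_plateau_sd = scene$bio_plateau_sd,
                 bio_gain_sd = scene$bio_gain_sd,
                 bio_green_sd = scene$bio_green_sd,
                 bio_rededge_sd_nm = scene$bio_rededge_sd_nm,
                 truth = unclass(scene$truth)),
    stages = config$stages, scales = config$scales,
    selectors = config$selectors,
    rf_thresholds = as.list(config$rf_thresholds),
    cars_runs = config$cars_runs, cv_folds = config$cv_folds,
    rf_iterations = config$rf_iterations, cap = config$cap,
    glcm_levels = config$glcm_levels, glcm_distance = config$glcm_distance,
    seed = config$seed, with_images = config$with_images)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Image-feature tables at selected characteristic wavelengths
#'
#' Re-renders each leaf of a campaign subset, calibrates and segments it,
#' builds the wavelet-coefficient grayscale image at each characteristic
#' wavelength and extracts 24 texture features and 3 color moments per
#' image, yielding `wavelengths x 24` texture and `wavelengths x 3` color
#' columns per sample with the standard naming scheme.
#'
#' @param campaign a [generate_campaign()] result.
#' @param rows row indices of `campaign$samples` to process.
#' @param scale_exponent CWT scale exponent for the grayscale database.
#' @param wavelengths_nm characteristic wavelengths (nm).
#' @param glcm_levels,glcm_distance GLCM settings.
#' @param raw_band use raw band images instead of coefficient images.
#' @return List of matrices `texture` and `color` (rows align with `rows`).
#' @export
image_feature_tables <- function(campaign, rows, scale_exponent,
                                 wavelengths_nm, glcm_levels = 256L,
                                 glcm_distance = 1L, raw_band = FALSE) {
  cfg <- campaign$config
  tex <- NULL; col <- NULL
  for (ri in seq_along(rows)) {
    sc <- campaign$render(rows[ri])
    refl <- calibrate_reflectance(sc$cube,
                                  panel_reflectance = cfg$panel_reflectance)
    mask <- segment_leaf(refl)
    cube <- trim_bands(refl)
    tex_row <- numeric(0); col_row <- numeric(0)
    for (wl in wavelengths_nm) {
      img <- coefficient_image(cube, mask, scale_exponent, wl,
                               raw_band = raw_band)
      tex_row <- c(tex_row, texture_features(img, mask, wl,
                                             distance = glcm_distance,
                                             levels = glcm_levels))
      col_row <- c(col_row, color_moments(img, mask, wl))
    }
    if (is.null(tex)) {
      tex <- matrix(NA_real_, length(rows), length(tex_row),
                    dimnames = list(NULL, names(tex_row)))
      col <- matrix(NA_real_, length(rows), length(col_row),
                    dimnames = list(NULL, names(col_row)))
    }
    tex[ri, ] <- tex_row
    col[ri, ] <- col_row
  }
  rownames(tex) <- rownames(col) <- campaign$samples$sample_id[rows]
  list(texture = tex, color = col)
}

# selected-feature matrix + wavelengths for one spectral set
select_spectral_set <- function(X, grid, k, selector, config, stage_seed,
                                threshold) {
  sel <- if (selector == "cars") {
    cars_select(X, k, n_runs = config$cars_runs, folds = config$cv_folds,
                seed = stage_seed, cap = config$cap)
  } else {
    random_frog_select(X, k, n_iter = config$rf_iterations,
                       threshold = threshold, seed = stage_seed,
                       folds = config$cv_folds, cap = config$cap)
  }
  idx <- sel$selected_indices
  if (length(idx) == 0) idx <- order(abs(cor(X, k)), decreasing = TRUE)[1:2]
  list(X = X[, idx, drop = FALSE], wavelengths = as.numeric(grid)[idx],
       selection = sel)
}

#' Run the full pipeline on one growth stage
#'
#' simulate -> calibrate -> segment -> mean spectra -> CWT -> characteristic
#' wavelength selection -> (optionally) grayscale-image features -> PLSR
#' comparison over scales, selectors and fusions.
#'
#' @param config a [run_config()].
#' @param stage stage name.
#' @param campaign optional pre-built campaign (defaults to generating one
#'   for this stage from the config).
#' @return List: `report` ([fuse_and_compare()] result), `samples`,
#'   `split`, `correlation_map`, `selections`, `image_selection`.
#' @export
run_stage <- function(config, stage, campaign = NULL) {
  stage_i <- match(stage, config$stages)
  stage_seed <- sub_seed(config$seed, 50000 + stage_i)
  if (is.null(campaign))
    campaign <- generate_campaign(config$scene, seed = sub_seed(config$seed, stage_i),
                                  stages = stage)
  rows <- which(campaign$samples$stage == stage)
  cs <- campaign_spectra(campaign)
  spectra <- cs$spectra[rows, , drop = FALSE]
  grid <- cs$grid
  k <- campaign$samples$k_percent[rows]
  split <- concentration_gradient_split(k, campaign$samples$sample_id[rows])
  stack <- cwt_stack(spectra, config$scales, grid)
  cmap <- correlation_map(stack, k)

  thr <- config$rf_thresholds
  threshold <- if (!is.null(names(thr)) && stage %in% names(thr))
    thr[[stage]] else thr[[min(stage_i, length(thr))]]

  spectral_sets <- list(); selections <- list()
  for (selector in config$selectors) {
    sets <- list()
    sel_R <- select_spectral_set(spectra, grid, k, selector, config,
                                 stage_seed, threshold)
    sets[["R"]] <- sel_R$X
    selections[[paste(selector, "R", sep = "-")]] <- sel_R
    for (sc in names(stack)) {
      sel <- select_spectral_set(stack[[sc]], grid, k, selector, config,
                                 stage_seed, threshold)
      sets[[sc]] <- sel$X
      selections[[paste(selector, sc, sep = "-")]] <- sel
    }
    spectral_sets[[selector]] <- sets
  }

  color <- NULL; texture <- NULL; image_sel <- NULL
  if (config$with_images) {
    # pick the provisional best CWT scale per validation R2 to build the
    # grayscale database, mirroring the per-stage best-scale workflow
    pre <- fuse_and_compare(spectral_sets, NULL, NULL, k, split,
                            stage = stage, seed = stage_seed)
    best <- pre$best_scale
    scale_exp <- as.integer(sub("CWT-", "", best$feature_set))
    wl <- selections[[paste(best$selector, best$feature_set, sep = "-")]]$wavelengths
    ift <- image_feature_tables(campaign, rows, scale_exp, wl,
                                config$glcm_levels, config$glcm_distance)
    tex_sel <- screen_image_features(ift$texture, k, seed = stage_seed,
                                     cap = config$cap,
                                     n_runs = config$cars_runs,
                                     folds = config$cv_folds)
    col_sel <- screen_image_features(ift$color, k, seed = stage_seed,
                                     cap = config$cap,
                                     n_runs = config$cars_runs,
                                     folds = config$cv_folds)
    texture <- ift$texture[, tex_sel$selected_indices, drop = FALSE]
    color <- ift$color[, col_sel$selected_indices, drop = FALSE]
    image_sel <- list(texture = tex_sel, color = col_sel,
                      scale_exponent = scale_exp, wavelengths = wl)
  }
  report <- fuse_and_compare(spectral_sets, color, texture, k, split,
                             stage = stage, seed = stage_seed)
  list(report = report, samples = campaign$samples[rows, ], split = split,
       correlation_map = cmap, selections = selections,
       image_selection = image_sel)
}

#' Run the full multi-stage pipeline
#'
#' Executes [run_stage()] for every configured stage and collects the
#' scale-comparison and fusion tables. Rerunning with the same config and
#' seed reproduces identical reports.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, [write_report()] is called.
#' @return A `pipeline_result`: `stages` (per-stage results), `scale_table`,
#'   `fusion_table`, `config`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stages <- lapply(config$stages, function(s) run_stage(config, s))
  names(stages) <- config$stages
  scale_table <- do.call(rbind, lapply(stages, function(s) s$report$scale_rows))
  fusion_table <- do.call(rbind, lapply(stages, function(s) s$report$fusion_rows))
  rownames(scale_table) <- NULL
  if (!is.null(fusion_table)) rownames(fusion_table) <- NULL
  out <- structure(list(stages = stages, scale_table = scale_table,
                        fusion_table = fusion_table, config = config),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d stage(s), %d scale rows, %d fusion rows\n",
              length(x$stages), nrow(x$scale_table),
              if (is.null(x$fusion_table)) 0L else nrow(x$fusion_table)))
  invisible(x)
}

#' Persist pipeline outputs
#'
#' Writes the scale-comparison and fusion tables as CSV, a per-stage
#' correlation-map CSV and grayscale heatmap PNG, the selected wavelengths,
#' and a YAML run manifest from which the exact configuration can be
#' reconstructed with [read_run_config()].
#'
#' @param result a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("write_report: cannot create directory ", outdir, call. = FALSE)
  files <- character(0)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(result$scale_table, "scale_comparison.csv")
  if (!is.null(result$fusion_table)) wr(result$fusion_table, "fusion_comparison.csv")
  for (s in names(result$stages)) {
    st <- result$stages[[s]]
    cm <- st$correlation_map
    wr(as.data.frame(cm$abs_r), sprintf("correlation_map_%s.csv", s))
    p <- file.path(outdir, sprintf("correlation_map_%s.png", s))
    png::writePNG(cm$abs_r[nrow(cm$abs_r):1, , drop = FALSE], p)
    files <- c(files, p)
    selw <- do.call(rbind, lapply(names(st$selections), function(nm) {
      data.frame(set = nm,
                 wavelength_nm = st$selections[[nm]]$wavelengths,
                 stringsAsFactors = FALSE)
    }))
    wr(selw, sprintf("selected_wavelengths_%s.csv", s))
  }
  manifest <- file.path(outdir, "run_manifest.yaml")
  write_run_config(result$config, manifest)
  files <- c(files, manifest)
  invisible(files)
}
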