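#' Convert a DN cube to reflectance against the gray reference panel
#'
#' Per band, reflectance is `dn / mean(panel dn) * panel_reflectance`, so the
#' panel maps to its nominal reflectance and any global illumination gain
#' cancels exactly.
#'
#' @param cube_dn a DN [hypercube()].
#' @param panel_region logical rows x cols matrix; defaults to the cube's
#'   declared panel region.
#' @param panel_reflectance nominal panel reflectance in (0, 1].
#' @param dark_current DN offset subtracted from both leaf and panel counts
#'   before ratioing (0 keeps the raw ratio).
#' @return A reflectance [hypercube()].
#' @export
calibrate_reflectance <- function(cube_dn, panel_region = cube_dn$panel_region,
                                  panel_reflectance = 0.60, dark_current = 0) {
  if (is.null(panel_region) || !any(panel_region))
    stop("calibrate_reflectance: panel region is empty", call. = FALSE)
  if (cube_dn$units != "dn")
    stop("calibrate_reflectance: cube is already in reflectance units", call. = FALSE)
  d <- dim(cube_dn$values)
  vals <- cube_dn$values - dark_current
  flat <- matrix(vals, d[1] * d[2], d[3])
  panel_mean <- colMeans(flat[which(panel_region), , drop = FALSE])
  bad <- which(panel_mean <= 0)
  if (length(bad) > 0)
    stop("calibrate_reflectance: non-positive panel mean in band(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  refl <- sweep(flat, 2, panel_mean, "/") * panel_reflectance
  hypercube(array(refl, d), cube_dn$grid, units = "reflectance",
            panel_region = cube_dn$panel_region,
            background_region = cube_dn$background_region)
}

# 4-connected components by vectorised frontier flood fill;
# returns integer label matrix (0 = background)
label_components <- function(mask) {
  rows <- nrow(mask); cols <- ncol(mask)
  labels <- matrix(0L, rows, cols)
  remaining <- which(mask)
  lab <- 0L
  while (length(remaining) > 0) {
    lab <- lab + 1L
    frontier <- remaining[1]
    labels[frontier] <- lab
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% rows + 1L
      c <- (frontier - 1L) %/% rows + 1L
      nb <- c(frontier[r > 1L] - 1L, frontier[r < rows] + 1L,
              frontier[c > 1L] - rows, frontier[c < cols] + rows)
      nb <- unique(nb[mask[nb] & labels[nb] == 0L])
      labels[nb] <- lab
      frontier <- nb
    }
    remaining <- remaining[labels[remaining] == 0L]
  }
  labels
}

#' Segment the leaf by single-band thresholding at 800 nm
#'
#' Pixels at or above the reflectance threshold in the band nearest `band_nm`
#' are leaf candidates; the declared panel region is excluded and only the
#' largest 4-connected component is kept, dropping speckle and panel
#' remnants. Reflectance below the threshold is background plate.
#'
#' @param cube a reflectance [hypercube()].
#' @param band_nm segmentation wavelength (nearest band center is used).
#' @param low lower reflectance cut; background lies below it.
#' @return Logical leaf mask, rows x cols.
#' @export
segment_leaf <- function(cube, band_nm = 800, low = 0.25) {
  if (cube$units != "reflectance")
    stop("segment_leaf: calibrate the cube to reflectance first", call. = FALSE)
  img <- band_image(cube, band_nm)
  mask <- img >= low
  if (!is.null(cube$panel_region)) mask[cube$panel_region] <- FALSE
  if (!any(mask))
    stop("segment_leaf: empty mask at ", band_nm, " nm / threshold ", low,
         call. = FALSE)
  labels <- label_components(mask)
  counts <- tabulate(labels[labels > 0L])
  labels == which.max(counts)
}

#' Mean spectrum over a pixel mask
#'
#' @param cube a [hypercube()].
#' @param mask logical rows x cols matrix with at least one TRUE pixel.
#' @return Numeric per-band arithmetic mean over masked pixels.
#' @export
mean_spectrum <- function(cube, mask) {
  d <- dim(cube$values)
  if (!all(dim(mask) == d[1:2]))
    stop("mean_spectrum: mask and cube shapes differ", call. = FALSE)
  if (!any(mask)) stop("mean_spectrum: empty mask", call. = FALSE)
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  colMeans(flat[which(mask), , drop = FALSE])
}

#' Laboratory potassium content from flame-photometry assay readings
#'
#' `K(%) = rho * V * t_s * 1e-4 / m`, with `rho` the K mass concentration
#' read off the standard curve (ug/mL), `V` the measuring liquid volume (mL),
#' `t_s` the unitless separation multiple and `m` the dry sample mass (g).
#'
#' @param rho mass concentration, ug/mL (>= 0).
#' @param volume measuring liquid volume, mL (> 0).
#' @param ts separation multiple (> 0).
#' @param mass dry sample mass, g (> 0).
#' @return Potassium content, % of dry mass.
#' @examples
#' lab_k_percent(50, 100, 10, 0.5)  # 10
#' @export
lab_k_percent <- function(rho, volume, ts, mass) {
  if (any(mass <= 0)) stop("lab_k_percent: mass must be > 0", call. = FALSE)
  if (any(rho < 0) || any(volume <= 0) || any(ts <= 0))
    stop("lab_k_percent: rho must be >= 0; volume and ts > 0", call. = FALSE)
  rho * volume * ts * 1e-4 / mass
}

#' Preprocess a campaign into per-leaf mean spectra
#'
#' Streams through a campaign: renders each scene, calibrates to reflectance,
#' segments the leaf, extracts the masked mean spectrum and trims it to the
#' working wavelength window. Cubes are discarded after use.
#'
#' @param campaign a [generate_campaign()] result.
#' @param lo_nm,hi_nm retained wavelength window, nm.
#' @return List: `spectra` (samples x bands matrix), `grid` (trimmed
#'   [band_grid()]), `samples` (the campaign sample table).
#' @export
campaign_spectra <- function(campaign, lo_nm = 400, hi_nm = 950) {
  cfg <- campaign$config
  n <- nrow(campaign$samples)
  spec <- NULL; grid <- NULL
  for (i in seq_len(n)) {
    sc <- campaign$render(i)
    refl <- calibrate_reflectance(sc$cube,
                                  panel_reflectance = cfg$panel_reflectance)
    mask <- segment_leaf(refl)
    s <- mean_spectrum(refl, mask)
    tr <- trim_bands(s, refl$grid, lo_nm, hi_nm)
    if (is.null(spec)) {
      grid <- tr$grid
      spec <- matrix(NA_real_, n, length(grid))
    }
    spec[i, ] <- tr$x
  }
  colnames(spec) <- sprintf("%.1fnm", as.numeric(grid))
  rownames(spec) <- campaign$samples$sample_id
  list(spectra = spec, grid = grid, samples = campaign$samples)
}
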