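#' Hyperspectral image cube
#'
#' Thin container for a rows x cols x bands array plus its band grid and the
#' declared reference-panel / background-plate regions (logical rows x cols
#' masks). `units` is `"dn"` for raw sensor counts or `"reflectance"` after
#' panel calibration.
#'
#' @param values numeric 3-D array, rows x cols x bands.
#' @param grid [band_grid()] of length `dim(values)[3]`.
#' @param units `"dn"` or `"reflectance"`.
#' @param panel_region,background_region logical rows x cols matrices (or
#'   NULL) marking the gray reference panel and the background plate.
#' @return A `hypercube` object (list).
#' @export
hypercube <- function(values, grid, units = c("dn", "reflectance"),
                      panel_region = NULL, background_region = NULL) {
  units <- match.arg(units)
  stopifnot(length(dim(values)) == 3, dim(values)[3] == length(grid))
  if (any(values < 0, na.rm = TRUE) && units == "dn")
    stop("hypercube: DN values must be >= 0", call. = FALSE)
  structure(list(values = values, grid = grid, units = units,
                 panel_region = panel_region,
                 background_region = background_region),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels, %d bands (%s), %.1f-%.1f nm\n",
              d[1], d[2], d[3], x$units, min(x$grid), max(x$grid)))
  invisible(x)
}

#' Extract one band of a cube as an image matrix
#' @param cube a [hypercube()].
#' @param nm wavelength; the nearest band center is used.
#' @return Numeric rows x cols matrix.
#' @export
band_image <- function(cube, nm) {
  cube$values[, , nearest_band(cube$grid, nm)]
}
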