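#' Build a uniform band-center wavelength grid
#'
#' The default grid reproduces a 128-band VNIR imaging spectrometer starting
#' at 376 nm: with 5.2 nm spacing the last center falls at 1036.4 nm and
#' exactly 106 centers lie inside the 400--950 nm working range that the rest
#' of the pipeline retains.
#'
#' @param n_bands number of band centers (>= 2).
#' @param start_nm wavelength of the first band center, nm.
#' @param spacing_nm spacing between adjacent centers, nm (> 0).
#' @return A `band_grid`: numeric vector of strictly increasing band centers
#'   (nm) with a `spacing` attribute.
#' @examples
#' g <- band_grid()
#' length(g)                       # 128
#' sum(g >= 400 & g <= 950)        # 106
#' @export
band_grid <- function(n_bands = 128L, start_nm = 376, spacing_nm = 5.2) {
  if (!is.numeric(n_bands) || n_bands < 2)
    stop("band_grid: n_bands must be >= 2", call. = FALSE)
  if (!is.numeric(spacing_nm) || spacing_nm <= 0)
    stop("band_grid: spacing_nm must be > 0", call. = FALSE)
  centers <- start_nm + spacing_nm * (seq_len(n_bands) - 1)
  structure(centers, spacing = spacing_nm, class = "band_grid")
}

#' @export
print.band_grid <- function(x, ...) {
  cat(sprintf("<band_grid> %d bands, %.1f-%.1f nm, spacing %.2f nm\n",
              length(x), x[1], x[length(x)], attr(x, "spacing")))
  invisible(x)
}

# subsetting keeps the grid class and spacing tag
#' @export
`[.band_grid` <- function(x, i) {
  structure(unclass(x)[i], spacing = attr(x, "spacing"), class = "band_grid")
}

#' Index of the band center nearest to a wavelength
#'
#' Ties between two equidistant centers resolve toward the lower center.
#'
#' @param grid a [band_grid()].
#' @param nm target wavelength, nm.
#' @return Integer band index into `grid`.
#' @export
nearest_band <- function(grid, nm) {
  d <- abs(as.numeric(grid) - nm)
  which.min(d)  # which.min takes the first (lower-wavelength) minimum on ties
}

#' Trim a spectrum, coefficient matrix or cube to a wavelength window
#'
#' Keeps bands whose centers satisfy `lo_nm <= center <= hi_nm` (closed
#' interval), preserving order. With the default sensor grid this retains the
#' 106 bands between 400 and 950 nm.
#'
#' @param x a numeric spectrum (length = bands), a matrix with bands as
#'   columns, or a [hypercube()].
#' @param grid the [band_grid()] describing `x` (taken from `x` for cubes).
#' @param lo_nm,hi_nm window bounds in nm.
#' @return A list with `x` (trimmed object) and `grid` (trimmed band grid);
#'   for hypercubes, a trimmed hypercube.
#' @export
trim_bands <- function(x, grid = NULL, lo_nm = 400, hi_nm = 950) {
  if (inherits(x, "hypercube")) {
    keep <- which(as.numeric(x$grid) >= lo_nm & as.numeric(x$grid) <= hi_nm)
    if (length(keep) == 0)
      stop("trim_bands: no band centers inside [", lo_nm, ", ", hi_nm, "] nm",
           call. = FALSE)
    x$values <- x$values[, , keep, drop = FALSE]
    x$grid <- x$grid[keep]
    return(x)
  }
  stopifnot(!is.null(grid))
  keep <- which(as.numeric(grid) >= lo_nm & as.numeric(grid) <= hi_nm)
  if (length(keep) == 0)
    stop("trim_bands: no band centers inside [", lo_nm, ", ", hi_nm, "] nm",
         call. = FALSE)
  xt <- if (is.matrix(x)) x[, keep, drop = FALSE] else x[keep]
  list(x = xt, grid = grid[keep])
}

# deterministic sub-seed derivation: one documented scheme everywhere, so each
# pipeline stage is independently reproducible from the run seed
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream)) %% 2147483647
}
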