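#' Write / read an ENVI-style hyperspectral cube
#'
#' ASCII `.hdr` header (with the wavelength list) plus a flat little-endian
#' binary in band-sequential (BSQ) or band-interleaved-by-line (BIL) order.
#' Values are written as 4-byte floats.
#'
#' @param cube a [hypercube()].
#' @param path base path; `.hdr` and `.dat` extensions are appended.
#' @param interleave `"bsq"` or `"bil"`.
#' @return `write_envi` returns `path` invisibly; `read_envi` returns a
#'   [hypercube()] (panel/background regions are not stored in the format).
#' @export
write_envi <- function(cube, path, interleave = c("bsq", "bil")) {
  interleave <- match.arg(interleave)
  d <- dim(cube$values)
  hdr <- c("ENVI",
           "description = {leafspec synthetic cube}",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = nm"),
           sprintf("wavelength = { %s }",
                   paste(sprintf("%.4f", as.numeric(cube$grid)), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  v <- cube$values
  ord <- if (interleave == "bsq") {
    # band-major, row-major within band
    as.numeric(aperm(v, c(2, 1, 3)))
  } else {
    # line-major, band, then sample
    as.numeric(aperm(v, c(2, 3, 1)))
  }
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(ord, con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  # headers may wrap the wavelength list over lines; rejoin before parsing
  joined <- paste(hdr, collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(joined, regexpr(sprintf("%s = [0-9]+", key), joined))
    as.integer(sub(sprintf("%s = ", key), "", m))
  }
  samples <- get_num("samples"); lines_n <- get_num("lines")
  bands <- get_num("bands")
  interleave <- sub(".*interleave = ([a-z]+).*", "\\1", joined)
  wl_txt <- sub(".*wavelength = \\{([^}]*)\\}.*", "\\1", joined)
  wl <- as.numeric(strsplit(wl_txt, ",")[[1]])
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  raw_v <- readBin(con, numeric(), n = samples * lines_n * bands, size = 4,
                   endian = "little")
  v <- if (interleave == "bsq") {
    aperm(array(raw_v, c(samples, lines_n, bands)), c(2, 1, 3))
  } else {
    aperm(array(raw_v, c(samples, bands, lines_n)), c(3, 1, 2))
  }
  spacing <- if (length(wl) > 1) wl[2] - wl[1] else 1
  grid <- structure(wl, spacing = spacing, class = "band_grid")
  units <- if (max(v) <= 1.2) "reflectance" else "dn"
  hypercube(v, grid, units = units)
}

#' Write / read a leaf mask as PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path PNG file path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}

#' Write a grayscale 8-bit image (e.g. a coefficient image) as PNG
#' @param image integer matrix 0..255.
#' @param path PNG file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a mean spectrum as CSV (wavelength_nm, reflectance)
#' @param spectrum numeric reflectance per band.
#' @param grid matching [band_grid()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, grid, path) {
  write.csv(data.frame(wavelength_nm = as.numeric(grid),
                       reflectance = spectrum),
            path, row.names = FALSE)
  invisible(path)
}

#' Write campaign ground truth as CSV
#' @param campaign a [generate_campaign()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_csv <- function(campaign, path) {
  write.csv(campaign$samples, path, row.names = FALSE)
  invisible(path)
}

#' Write one band of a cube as a 16-bit grayscale TIFF
#'
#' DN cubes are scaled by the 16-bit full range (65535); reflectance cubes
#' by their nominal maximum of 1.2.
#'
#' @param cube a [hypercube()].
#' @param nm wavelength; the nearest band center is written.
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
write_band_tiff <- function(cube, nm, path) {
  img <- band_image(cube, nm)
  full <- if (cube$units == "dn") 65535 else 1.2
  tiff::writeTIFF(pmin(pmax(img / full, 0), 1), path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a grayscale image database for one leaf
#'
#' Writes one PNG per characteristic wavelength, named
#' `{sample}_CWT-{scale}_{wavelength}nm.png`, each the min-max scaled
#' wavelet-coefficient image of [coefficient_image()].
#'
#' @param cube a reflectance [hypercube()] (trimmed to the working window).
#' @param mask logical leaf mask.
#' @param sample_id identifier used in file names.
#' @param scale_exponent CWT scale exponent.
#' @param wavelengths_nm characteristic wavelengths.
#' @param outdir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_grayscale_database <- function(cube, mask, sample_id, scale_exponent,
                                     wavelengths_nm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(wavelengths_nm, function(wl) {
    img <- coefficient_image(cube, mask, scale_exponent, wl)
    p <- file.path(outdir, sprintf("%s_CWT-%d_%gnm.png", sample_id,
                                   scale_exponent, wl))
    write_gray_png(img, p)
    p
  }, character(1))
  invisible(files)
}
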