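#' Hyperspectral cube container
#'
#' An `hsi_cube` holds a 3-D array of per-pixel spectra — dimensions
#' (row, col, band), 1-based, band axis last — together with the wavelength
#' (nm) of every band and a tag saying what the values mean.
#'
#' @param data Numeric 3-D array, dimensions (rows, cols, bands).
#' @param wavelengths Numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param value_kind One of `"raw"`, `"reflectance"`, `"absorbance"`, `"snv"`.
#'   Raw cubes must be non-negative (sensor counts).
#' @param bit_depth Integer, sensor bit depth (metadata only; default 14).
#'
#' @return An object of class `hsi_cube`: a list with elements `data`,
#'   `wavelengths`, `value_kind`, `bit_depth`.
#' @examples
#' wl <- wavelength_grid()
#' cube <- hsi_cube(array(1, c(2, 2, length(wl))), wl, "raw")
#' n_bands(cube)
#' @export
hsi_cube <- function(data, wavelengths, value_kind = "raw", bit_depth = 14L) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows, cols, bands)", call. = FALSE)
  storage.mode(data) <- "double"
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    stop("length(wavelengths) [", length(wavelengths),
         "] must equal the number of bands [", dim(data)[3L], "]",
         call. = FALSE)
  if (anyNA(wavelengths) || any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing and free of NA",
         call. = FALSE)
  value_kind <- match.arg(value_kind,
                          c("raw", "reflectance", "absorbance", "snv"))
  if (value_kind == "raw" && any(data < 0, na.rm = TRUE))
    stop("raw cubes must be non-negative", call. = FALSE)
  structure(
    list(data = data, wavelengths = wavelengths,
         value_kind = value_kind, bit_depth = as.integer(bit_depth)),
    class = "hsi_cube")
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' Number of spectral bands in a cube
#' @param cube An `hsi_cube`.
#' @return Integer band count.
#' @export
n_bands <- function(cube) length(cube$wavelengths)

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d px, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$value_kind))
  invisible(x)
}

#' Index of the band nearest a target wavelength
#'
#' Ties (a target exactly midway between two bands) resolve to the lower
#' wavelength.
#'
#' @param cube An `hsi_cube` (or a numeric wavelength vector).
#' @param nm Target wavelength in nm.
#' @return Integer band index.
#' @export
band_nearest <- function(cube, nm) {
  wl <- if (inherits(cube, "hsi_cube")) cube$wavelengths else as.numeric(cube)
  which.min(abs(wl - nm))  # which.min takes the first (lower-wavelength) tie
}

#' Default spectrometer wavelength grid
#'
#' The acquisition grid used throughout: 1000 nm upward in 6.3 nm steps, up
#' to 2350 nm (215 bands).
#'
#' @param from,to Grid limits in nm.
#' @param step Band spacing in nm.
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(from = 1000, to = 2350, step = 6.3) {
  from + step * seq(0L, floor((to - from) / step))
}

#' Calibration frame set
#'
#' Bundles the three aligned acquisitions needed for reflectance
#' calibration: the raw specimen frame, the white-standard frame and the
#' dark-noise frame.
#'
#' @param raw,white,dark `hsi_cube`s of identical shape and wavelength grid.
#' @return An object of class `calibration_set`.
#' @export
calibration_set <- function(raw, white, dark) {
  for (c_ in list(raw, white, dark))
    if (!inherits(c_, "hsi_cube")) stop("all inputs must be hsi_cube objects",
                                        call. = FALSE)
  if (!identical(dim(raw$data), dim(white$data)) ||
      !identical(dim(raw$data), dim(dark$data)))
    stop("raw, white and dark cubes must share the same shape", call. = FALSE)
  if (!isTRUE(all.equal(raw$wavelengths, white$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths)))
    stop("raw, white and dark cubes must share the same wavelength grid",
         call. = FALSE)
  structure(list(raw = raw, white = white, dark = dark),
            class = "calibration_set")
}

#' @export
print.calibration_set <- function(x, ...) {
  cat("<calibration_set>\n  raw:   "); print(x$raw)
  cat("  white: "); print(x$white)
  cat("  dark:  "); print(x$dark)
  invisible(x)
}
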