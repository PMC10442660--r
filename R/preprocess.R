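#' Preprocessing parameters
#'
#' Defaults follow the acquisition protocol the pipeline models: bands above
#' 1400 nm are dropped (strong water absorption, poor detector sensitivity),
#' specular highlights are pixels whose reflectance at the band nearest
#' 1300 nm exceeds 70%, shadows fall below 10%, and a 5-pixel margin around
#' the freehand pathologist boundary lines is excluded because the lines are
#' drawn by hand and carry positional uncertainty.
#'
#' @param keep_window Length-2 numeric, wavelength window (nm) retained for
#'   analysis, inclusive on both ends.
#' @param highlight_threshold,shadow_threshold Reflectance fractions in
#'   `[0, 1]`; `shadow < highlight` required.
#' @param reference_wavelength Wavelength (nm) whose nearest band is used for
#'   the highlight/shadow test.
#' @param margin_px Chebyshev radius (pixels) of the exclusion zone dilated
#'   around every boundary-line pixel.
#' @param epsilon Small positive guard for divisions and logs.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(keep_window = c(1000, 1400),
                              highlight_threshold = 0.70,
                              shadow_threshold = 0.10,
                              reference_wavelength = 1300,
                              margin_px = 5L,
                              epsilon = 1e-6) {
  stopifnot(length(keep_window) == 2L, keep_window[1] < keep_window[2],
            shadow_threshold >= 0, highlight_threshold <= 1,
            shadow_threshold < highlight_threshold,
            margin_px >= 0, epsilon > 0)
  structure(list(keep_window = as.numeric(keep_window),
                 highlight_threshold = highlight_threshold,
                 shadow_threshold = shadow_threshold,
                 reference_wavelength = reference_wavelength,
                 margin_px = as.integer(margin_px),
                 epsilon = epsilon),
            class = "preprocess_params")
}

flagged_pixels <- function(cube) {
  f <- attr(cube, "flagged")
  if (is.null(f)) matrix(FALSE, dim(cube)[1], dim(cube)[2]) else f
}

#' Reflectance calibration against white and dark frames
#'
#' Per pixel and band, reflectance is `R = (Ir - Id) / (Iw - Id)` with `Ir`
#' the raw frame, `Iw` the white standard and `Id` the dark noise. Pixels
#' where the white-dark difference is not positive (dead or unlit sensor
#' positions) are flagged rather than producing non-finite values; the flag
#' propagates into [build_validity_mask()] as a shadow exclusion.
#'
#' @param cal A [calibration_set].
#' @param epsilon Positive guard: a pixel is flagged wherever
#'   `Iw - Id <= epsilon` at any band.
#' @return An [hsi_cube] with `value_kind = "reflectance"` and a `"flagged"`
#'   attribute (logical matrix of degenerate pixels).
#' @export
compute_reflectance <- function(cal, epsilon = 1e-6) {
  if (!inherits(cal, "calibration_set"))
    stop("`cal` must be a calibration_set", call. = FALSE)
  denom <- cal$white$data - cal$dark$data
  bad_band <- denom <= epsilon
  flagged <- apply(bad_band, c(1L, 2L), any)
  denom[bad_band] <- 1  # placeholder; flagged pixels are excluded downstream
  r <- (cal$raw$data - cal$dark$data) / denom
  r[bad_band] <- 0
  cube <- hsi_cube(r, cal$raw$wavelengths, value_kind = "reflectance",
                   bit_depth = cal$raw$bit_depth)
  attr(cube, "flagged") <- flagged
  cube
}

#' Absorbance from calibrated reflectance
#'
#' `A = -log10(R)` with `R` clamped below at `epsilon` so that shadow pixels
#' yield large-but-finite absorbance instead of `Inf`.
#'
#' @inheritParams compute_reflectance
#' @return An [hsi_cube] with `value_kind = "absorbance"`; the degenerate
#'   pixel flag is carried over.
#' @export
compute_absorbance <- function(cal, epsilon = 1e-6) {
  refl <- compute_reflectance(cal, epsilon)
  a <- -log10(pmax(refl$data, epsilon))
  cube <- hsi_cube(a, refl$wavelengths, value_kind = "absorbance",
                   bit_depth = refl$bit_depth)
  attr(cube, "flagged") <- attr(refl, "flagged")
  cube
}

#' Standard normal variate (SNV) transform
#'
#' Each pixel's spectrum is centred and scaled along the band axis:
#' `Z = (x - mean(x)) / sd(x)`, using the sample standard deviation
#' (denominator n-1, the SNV-literature convention; a population-sd variant
#' is available since the two differ only by a factor common to all pixels
#' and leave classification unchanged). Constant spectra (zero sd) are
#' flagged, not raised.
#'
#' @param cube An [hsi_cube] (typically absorbance, after window trimming).
#' @param sd_denom `"sample"` (n-1) or `"population"` (n).
#' @return An [hsi_cube] with `value_kind = "snv"` and an updated `"flagged"`
#'   attribute.
#' @export
snv_transform <- function(cube, sd_denom = c("sample", "population")) {
  sd_denom <- match.arg(sd_denom)
  if (!inherits(cube, "hsi_cube")) stop("`cube` must be an hsi_cube",
                                        call. = FALSE)
  nb <- n_bands(cube)
  if (nb < 2L) stop("SNV needs at least 2 bands", call. = FALSE)
  d <- dim(cube$data)
  x <- matrix(cube$data, d[1L] * d[2L], d[3L])  # pixels x bands
  mu <- rowMeans(x)
  cent <- x - mu
  ss <- rowSums(cent^2)
  denom <- if (sd_denom == "sample") nb - 1L else nb
  s <- sqrt(ss / denom)
  const <- s <= .Machine$double.eps * 100
  s[const] <- 1
  z <- cent / s
  z[const, ] <- 0
  cube_out <- hsi_cube(array(z, d), cube$wavelengths, value_kind = "snv",
                       bit_depth = cube$bit_depth)
  attr(cube_out, "flagged") <- flagged_pixels(cube) |
    matrix(const, d[1L], d[2L])
  cube_out
}

#' Trim a cube to a wavelength window
#'
#' Retains exactly the bands with `window[1] <= lambda <= window[2]`,
#' preserving order. The default analysis window keeps 1000-1400 nm.
#'
#' @param cube An [hsi_cube].
#' @param window Length-2 numeric interval in nm (inclusive).
#' @return The trimmed [hsi_cube]; flags are carried over.
#' @export
trim_wavelengths <- function(cube, window = c(1000, 1400)) {
  if (!inherits(cube, "hsi_cube")) stop("`cube` must be an hsi_cube",
                                        call. = FALSE)
  keep <- cube$wavelengths >= window[1] & cube$wavelengths <= window[2]
  if (!any(keep))
    stop("no bands inside the window [", window[1], ", ", window[2], "] nm",
         call. = FALSE)
  out <- hsi_cube(cube$data[, , keep, drop = FALSE], cube$wavelengths[keep],
                  value_kind = cube$value_kind, bit_depth = cube$bit_depth)
  attr(out, "flagged") <- attr(cube, "flagged")
  out
}

#' Chebyshev dilation of a pixel coordinate set
#'
#' Every pixel within Chebyshev (chessboard) distance `radius` of a seed
#' pixel — the `(2r+1) x (2r+1)` square around it — is marked, clipped to
#' the raster. Used to realize the boundary-margin exclusion.
#'
#' @param coords Two-column (row, col) integer matrix of seed pixels.
#' @param radius Non-negative integer radius.
#' @param dims Raster dimensions `c(rows, cols)`.
#' @return Logical matrix of marked pixels.
#' @export
dilate_chebyshev <- function(coords, radius, dims) {
  out <- matrix(FALSE, dims[1L], dims[2L])
  if (is.null(coords) || nrow(coords) == 0L) return(out)
  offs <- seq.int(-radius, radius)
  for (dr in offs) {
    r <- coords[, 1L] + dr
    ok_r <- r >= 1L & r <= dims[1L]
    for (dc in offs) {
      c_ <- coords[, 2L] + dc
      ok <- ok_r & c_ >= 1L & c_ <= dims[2L]
      out[cbind(r[ok], c_[ok])] <- TRUE
    }
  }
  out
}

#' Build the per-pixel validity mask
#'
#' A pixel is excluded if it is (in decreasing precedence, which also
#' determines the recorded reason when several apply): outside the
#' pathologically evaluated area; labelled necrosis; a specular highlight
#' (reflectance at the reference band above the highlight threshold) or a
#' shadow (below the shadow threshold, or flagged degenerate during
#' calibration); or within `margin_px` Chebyshev distance of any
#' boundary-line pixel.
#'
#' @param reflectance An [hsi_cube] with `value_kind = "reflectance"`
#'   containing the reference band.
#' @param annotation An [annotation_map] of the same spatial shape.
#' @param params A [preprocess_params].
#' @param extra_invalid Optional logical matrix of additional degenerate
#'   pixels (e.g. constant spectra flagged by [snv_transform()]); excluded
#'   with reason `"shadow"`.
#' @return A [validity_mask].
#' @export
build_validity_mask <- function(reflectance, annotation, params,
                                extra_invalid = NULL) {
  stopifnot(inherits(reflectance, "hsi_cube"),
            inherits(annotation, "annotation_map"),
            inherits(params, "preprocess_params"))
  dims <- dim(reflectance)[1:2]
  if (!identical(dims, dim(annotation$labels)))
    stop("reflectance cube and annotation shapes differ", call. = FALSE)
  ref_band <- band_nearest(reflectance, params$reference_wavelength)
  r_ref <- reflectance$data[, , ref_band]

  outside <- annotation$labels == LABELS[["outside_evaluated"]]
  necrosis <- annotation$labels == LABELS[["necrosis"]]
  highlight <- r_ref > params$highlight_threshold
  shadow <- r_ref < params$shadow_threshold | flagged_pixels(reflectance)
  if (!is.null(extra_invalid)) shadow <- shadow | extra_invalid
  margin <- dilate_chebyshev(rbind(annotation$tumor_boundary,
                                   annotation$exposure_boundary),
                             params$margin_px, dims)

  reason <- matrix(NA_character_, dims[1L], dims[2L])
  reason[margin] <- "boundary_margin"
  reason[shadow] <- "shadow"
  reason[highlight] <- "highlight"
  reason[necrosis] <- "necrosis"
  reason[outside] <- "outside_evaluated"
  validity_mask(is.na(reason), reason)
}

#' Preprocess one specimen end to end
#'
#' Runs the calibration chain on a specimen's frames: reflectance,
#' absorbance, wavelength trimming, SNV, and the validity mask.
#'
#' @param specimen A list with elements `calibration` (a [calibration_set])
#'   and `annotation` (an [annotation_map]), e.g. a [simulate_specimen()]
#'   result; an optional `id` is carried through.
#' @param params A [preprocess_params].
#' @return A list of class `preprocessed_specimen`: `snv` (trimmed SNV cube),
#'   `reflectance` (trimmed), `mask`, `annotation`, `id`.
#' @export
preprocess_specimen <- function(specimen, params = preprocess_params()) {
  refl <- compute_reflectance(specimen$calibration, params$epsilon)
  absb <- compute_absorbance(specimen$calibration, params$epsilon)
  refl_t <- trim_wavelengths(refl, params$keep_window)
  absb_t <- trim_wavelengths(absb, params$keep_window)
  snv <- snv_transform(absb_t)
  mask <- build_validity_mask(refl_t, specimen$annotation, params,
                              extra_invalid = flagged_pixels(snv))
  structure(list(snv = snv, reflectance = refl_t, mask = mask,
                 annotation = specimen$annotation,
                 id = specimen$id %||% NA_character_),
            class = "preprocessed_specimen")
}
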