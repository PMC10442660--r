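# Synthetic specimens: a two-layer Beer-Lambert stand-in for resected
# gastric specimens under NIR-HSI. Tumor signal saturates with tumor
# thickness and is attenuated exponentially by covering normal mucosa.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

gauss_peak <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

#' Synthetic endmember absorbance spectra
#'
#' Builds one absorbance spectrum per tissue class as a sum of Gaussian
#' peaks on the wavelength grid, with small seeded jitter on peak positions
#' and amplitudes to emulate inter-specimen biochemical variation. The pair
#' is constructed so that, after SNV transformation on the 1000-1400 nm
#' window, the tumor-minus-normal difference is negative around 1050-1100 nm
#' and 1380-1400 nm and positive around 1250-1350 nm — the spectral
#' signature the classifier exploits.
#'
#' @param grid Wavelength vector (nm); must cover at least 1000-1400 nm.
#' @param seed Integer seed for the jitter.
#' @param jitter_sd Relative amplitude jitter (and 1/3 of the nm jitter on
#'   peak centers); 0 gives the nominal pair.
#' @return List with elements `normal` and `tumor`, numeric vectors on
#'   `grid`.
#' @export
make_endmembers <- function(grid, seed = 1L, jitter_sd = 0.03) {
  if (min(grid) > 1000 || max(grid) < 1400)
    stop("wavelength grid must cover 1000-1400 nm (got ",
         min(grid), "-", max(grid), " nm)", call. = FALSE)
  local_seed(seed, {
    j <- function(x) x * (1 + stats::rnorm(1L, 0, jitter_sd))
    s <- function() stats::rnorm(1L, 0, 3 * jitter_sd / 0.03)
    normal <- 0.50 +
      j(0.30) * gauss_peak(grid, 1078 + s(), 42) +
      j(0.20) * gauss_peak(grid, 1395 + s(), 45) +
      j(0.10) * gauss_peak(grid, 1550 + s(), 120) +
      j(0.35) * gauss_peak(grid, 1930 + s(), 90)
    tumor <- 0.50 +
      j(0.16) * gauss_peak(grid, 1078 + s(), 42) +
      j(0.30) * gauss_peak(grid, 1302 + s(), 55) +
      j(0.10) * gauss_peak(grid, 1395 + s(), 45) +
      j(0.10) * gauss_peak(grid, 1550 + s(), 120) +
      j(0.35) * gauss_peak(grid, 1930 + s(), 90)
    list(normal = normal, tumor = tumor)
  })
}

#' Tumor mixing weight of the two-layer model
#'
#' The per-pixel absorbance is a convex-like blend
#' `A = A_normal + w * (A_tumor - A_normal)` with
#' `w = (1 - exp(-k_t * t_tumor)) * exp(-attenuation_k * t_cover)`:
#' the tumor contribution saturates with tumor thickness `t_tumor` (mm) and
#' decays exponentially with the thickness `t_cover` (mm) of normal mucosa
#' covering it. `w` is strictly increasing in `t_tumor` and strictly
#' decreasing in `t_cover`.
#'
#' @param t_tumor Tumor thickness, mm (>= 0).
#' @param t_cover Covering-mucosa thickness, mm (0 on exposed pixels).
#' @param k_t Tumor-thickness saturation constant, 1/mm.
#' @param attenuation_k Covering-mucosa attenuation constant, 1/mm.
#' @return Numeric weight(s) in `[0, 1)`.
#' @export
tumor_weight <- function(t_tumor, t_cover, k_t, attenuation_k) {
  (1 - exp(-k_t * t_tumor)) * exp(-attenuation_k * t_cover)
}

#' Synthetic-specimen configuration
#'
#' Defaults define the reference simulation conditions used across tests:
#' a 90 x 110 px specimen on the full acquisition grid, an elliptical tumor
#' with an exposed core and (optionally) an unexposed rim, tumor thickness
#' tapering linearly from `t_max_mm` at the center to 0 at the tumor
#' boundary, covering mucosa ramping from 0 at the exposure boundary to
#' `cover_max_mm` at the tumor boundary, plus highlight/shadow/necrosis
#' artifacts and additive Gaussian sensor noise.
#'
#' @param shape `c(rows, cols)` in pixels.
#' @param wavelengths Acquisition grid, nm.
#' @param endmembers `NULL` (generated per seed via [make_endmembers()]) or
#'   a list with `normal` and `tumor` spectra on `wavelengths`.
#' @param k_t Tumor-thickness saturation constant, 1/mm.
#' @param attenuation_k Covering-mucosa attenuation constant, 1/mm.
#' @param t_max_mm Maximum tumor thickness at the tumor center, mm.
#' @param cover_max_mm Covering-mucosa thickness at the tumor boundary, mm.
#' @param tumor_geometry List: `a_frac`, `b_frac` (tumor semi-axes as
#'   fractions of rows/cols), `core_frac` (exposed core as a fraction of the
#'   tumor's radial extent; `>= 1` means fully exposed, no unexposed rim).
#' @param noise_sd Additive intensity noise SD, sensor counts.
#' @param artifact_counts List: numbers of `highlight`, `shadow`, `necrosis`
#'   blobs.
#' @param white_level,dark_level Nominal white-standard and dark-noise
#'   counts.
#' @param seed Integer seed; the specimen is a deterministic function of its
#'   config.
#' @return An object of class `specimen_config`.
#' @export
specimen_config <- function(shape = c(120L, 150L),
                            wavelengths = wavelength_grid(),
                            endmembers = NULL,
                            k_t = 0.13,
                            attenuation_k = 0.4,
                            t_max_mm = 12,
                            cover_max_mm = 3,
                            tumor_geometry = list(a_frac = 0.34,
                                                  b_frac = 0.32,
                                                  core_frac = 0.5),
                            noise_sd = 220,
                            artifact_counts = list(highlight = 2L,
                                                   shadow = 2L,
                                                   necrosis = 1L),
                            white_level = 8000,
                            dark_level = 500,
                            seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 20L),
            k_t > 0, attenuation_k > 0, t_max_mm > 0, cover_max_mm >= 0,
            noise_sd >= 0)
  structure(list(shape = as.integer(shape), wavelengths = wavelengths,
                 endmembers = endmembers, k_t = k_t,
                 attenuation_k = attenuation_k, t_max_mm = t_max_mm,
                 cover_max_mm = cover_max_mm, tumor_geometry = tumor_geometry,
                 noise_sd = noise_sd, artifact_counts = artifact_counts,
                 white_level = white_level, dark_level = dark_level,
                 seed = as.integer(seed)),
            class = "specimen_config")
}

# pixels tracing the boundary of a logical region (region pixels with a
# 4-neighbour outside the region)
region_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !interior, arr.ind = TRUE)
}

disc_mask <- function(dims, center, radius) {
  rr <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  cc <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  (rr - center[1L])^2 + (cc - center[2L])^2 <= radius^2
}

#' Simulate one synthetic specimen
#'
#' Generates the three calibration cubes (raw, white, dark), the annotation
#' map (labels, boundary lines, thickness raster) and records the config as
#' provenance. The forward model per pixel: absorbance
#' `A = A_n + w (A_t - A_n)` with `w` from [tumor_weight()], raw intensity
#' `Ir = Id + (Iw - Id) 10^(-A) + noise`. Highlight and shadow blobs force
#' the computed 1300 nm reflectance above 0.7 / below 0.1 respectively;
#' necrosis blobs inside the tumor get a distinct spectrum and are labelled
#' for exclusion. Deterministic under a fixed config (including seed).
#'
#' @param config A [specimen_config].
#' @param id Optional specimen identifier carried through the pipeline.
#' @return A list of class `synthetic_specimen` with elements `calibration`
#'   ([calibration_set]), `annotation` ([annotation_map]), `cover_mm`
#'   (covering-mucosa thickness raster), `config`, `id`.
#' @export
simulate_specimen <- function(config, id = "s1") {
  stopifnot(inherits(config, "specimen_config"))
  local_seed(config$seed, {
    nr <- config$shape[1L]; nc <- config$shape[2L]
    wl <- config$wavelengths; nb <- length(wl)
    em <- config$endmembers %||%
      make_endmembers(wl, seed = config$seed)
    stopifnot(length(em$normal) == nb, length(em$tumor) == nb)

    # geometry: evaluated ellipse fills the frame; tumor ellipse jittered
    rr <- matrix(seq_len(nr), nr, nc)
    cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ev_rho <- sqrt(((rr - (nr + 1) / 2) / (0.48 * nr))^2 +
                   ((cc - (nc + 1) / 2) / (0.48 * nc))^2)
    evaluated <- ev_rho <= 1
    g <- config$tumor_geometry
    ctr <- c((nr + 1) / 2 + stats::runif(1, -0.04, 0.04) * nr,
             (nc + 1) / 2 + stats::runif(1, -0.04, 0.04) * nc)
    a <- g$a_frac * nr * stats::runif(1, 0.9, 1.1)
    b <- g$b_frac * nc * stats::runif(1, 0.9, 1.1)
    rho <- sqrt(((rr - ctr[1L]) / a)^2 + ((cc - ctr[2L]) / b)^2)
    tumor <- rho < 1 & evaluated
    core_frac <- min(g$core_frac, 1)
    exposed <- tumor & rho <= core_frac

    # thickness: tumor tapers linearly center -> 0 at the white line;
    # cover ramps 0 at the yellow line -> cover_max at the white line
    t_tumor <- ifelse(tumor, config$t_max_mm * (1 - rho), 0)
    t_cover <- matrix(0, nr, nc)
    if (core_frac < 1) {
      rim <- tumor & rho > core_frac
      t_cover[rim] <- config$cover_max_mm *
        (rho[rim] - core_frac) / (1 - core_frac)
    }

    labels <- matrix(LABELS[["outside_evaluated"]], nr, nc)
    labels[evaluated] <- LABELS[["normal"]]
    labels[tumor & t_cover == 0] <- LABELS[["exposed_tumor"]]
    labels[tumor & t_cover > 0] <- LABELS[["unexposed_tumor"]]

    w <- tumor_weight(t_tumor, t_cover, config$k_t, config$attenuation_k)

    # absorbance cube: A = A_n + w (A_t - A_n)
    npix <- nr * nc
    A <- outer(as.vector(w), em$tumor - em$normal) +
      rep(em$normal, each = npix)

    # necrosis blobs inside the tumor core
    n_nec <- config$artifact_counts$necrosis %||% 0L
    nec <- matrix(FALSE, nr, nc)
    core_idx <- which(exposed)
    if (n_nec > 0L && length(core_idx) > 20L) {
      for (i in seq_len(n_nec)) {
        ci <- core_idx[sample.int(length(core_idx), 1L)]
        d <- disc_mask(c(nr, nc), c(row(labels)[ci], col(labels)[ci]),
                       stats::runif(1, 2, 3.5)) & tumor
        nec <- nec | d
      }
      labels[nec] <- LABELS[["necrosis"]]
      t_tumor[nec] <- 0
      A[as.vector(nec), ] <- rep(0.8 * em$normal + 0.25, each = sum(nec))
    }

    # highlight / shadow artifact discs (flat absorbance => flat reflectance)
    place_discs <- function(k, a_flat) {
      ev_idx <- which(evaluated & !nec)
      for (i in seq_len(k)) {
        ci <- ev_idx[sample.int(length(ev_idx), 1L)]
        d <- disc_mask(c(nr, nc), c(row(labels)[ci], col(labels)[ci]),
                       stats::runif(1, 1.5, 3))
        A[as.vector(d), ] <<- a_flat
      }
    }
    place_discs(config$artifact_counts$highlight %||% 0L, -log10(0.80))
    place_discs(config$artifact_counts$shadow %||% 0L, -log10(0.05))

    # forward model to sensor counts
    iw <- config$white_level +
      0.18 * config$white_level * exp(-((wl - 1500) / 500)^2)
    iw_cube <- array(rep(iw, each = npix), c(nr, nc, nb))
    id_cube <- array(config$dark_level, c(nr, nc, nb))
    ir <- id_cube + (iw_cube - id_cube) * array(10^(-A), c(nr, nc, nb))
    if (config$noise_sd > 0)
      ir <- ir + array(stats::rnorm(npix * nb, 0, config$noise_sd),
                       c(nr, nc, nb))
    ir <- pmax(ir, 0)

    ann <- annotation_map(
      labels,
      tumor_boundary = region_boundary(tumor),
      exposure_boundary = if (core_frac < 1 && any(labels ==
        LABELS[["unexposed_tumor"]])) region_boundary(exposed) else NULL,
      thickness_mm = t_tumor)

    structure(
      list(calibration = calibration_set(
             raw = hsi_cube(ir, wl, "raw"),
             white = hsi_cube(iw_cube, wl, "raw"),
             dark = hsi_cube(id_cube, wl, "raw")),
           annotation = ann,
           cover_mm = t_cover,
           config = config,
           id = id),
      class = "synthetic_specimen")
  })
}

#' Simulate a cohort of synthetic specimens
#'
#' Mirrors the reference study design: `n` specimens (default 10) with
#' varied geometry and endmember jitter, of which `n_unexposed` (default 6
#' of 10) carry an unexposed tumor rim and the rest are fully exposed.
#'
#' @param n Number of specimens (>= 2; leave-one-out needs at least 2).
#' @param template A [specimen_config] providing shared parameters.
#' @param seed Master seed; per-specimen seeds are derived from it.
#' @param n_unexposed Number of specimens with an unexposed rim.
#' @return List of `synthetic_specimen`, ids `"a"`, `"b"`, ...
#' @export
simulate_cohort <- function(n = 10L, template = specimen_config(),
                            seed = 1L, n_unexposed = round(0.6 * n)) {
  if (n < 2L)
    stop("a cohort needs at least 2 specimens (leave-one-out ",
         "cross-validation is undefined for n = 1)", call. = FALSE)
  stopifnot(n_unexposed >= 0L, n_unexposed <= n)
  rim <- local_seed(seed, sample.int(n, n_unexposed))
  ids <- if (n <= 26L) letters[seq_len(n)] else sprintf("s%02d", seq_len(n))
  lapply(seq_len(n), function(i) {
    cfg <- template
    cfg$seed <- as.integer(seed + 7919L * i)
    cfg$tumor_geometry$core_frac <-
      if (i %in% rim) template$tumor_geometry$core_frac else 1
    simulate_specimen(cfg, id = ids[i])
  })
}
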