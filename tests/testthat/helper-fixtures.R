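# Shared fixtures. Expensive artifacts (the reference cohort run) are
# built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small, fast specimen for unit tests (same physics, smaller raster and
# a short wavelength grid that still covers the analysis window)
small_config <- function(seed = 11L,
                         artifact_counts = list(highlight = 1L,
                                                shadow = 1L,
                                                necrosis = 1L), ...) {
  specimen_config(shape = c(80L, 100L),
                  wavelengths = wavelength_grid(to = 1500),
                  artifact_counts = artifact_counts,
                  seed = seed, ...)
}

small_specimen <- function(seed = 11L, ...)
  simulate_specimen(small_config(seed = seed, ...), id = paste0("s", seed))

# a toy calibration set with hand-set constant frames
toy_calibration <- function(ir, iw, id, wl = c(1000, 1100, 1200, 1300)) {
  shape <- c(2L, 2L, length(wl))
  calibration_set(
    raw = hsi_cube(array(ir, shape), wl, "raw"),
    white = hsi_cube(array(iw, shape), wl, "raw"),
    dark = hsi_cube(array(id, shape), wl, "raw"))
}

# full reference pipeline run (default 10-specimen cohort), built once
default_run <- function()
  cached("default_run", run_all(pipeline_config(seed = 1L)))

# brute-force dual-QP SVM decision values (independent oracle, kernlab)
qp_oracle_decision <- function(X, y, C, sigma2, Xnew = X) {
  K <- exp(-as.matrix(stats::dist(X))^2 / sigma2)
  H <- outer(y, y) * K
  n <- nrow(X)
  sol <- kernlab::ipop(c = rep(-1, n), H = H, A = matrix(y, 1L), b = 0,
                       r = 0, l = rep(0, n), u = rep(C, n),
                       sigf = 9, maxiter = 100)
  alpha <- kernlab::primal(sol)
  free <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
  stopifnot(any(free))
  bias <- mean(vapply(which(free), function(i)
    y[i] - sum(alpha * y * K[i, ]), 0))
  d2 <- outer(rowSums(Xnew^2), rowSums(X^2), "+") - 2 * Xnew %*% t(X)
  Kn <- exp(-d2 / sigma2)
  as.vector(Kn %*% (alpha * y) + bias)
}

as_training_set <- function(X, labels) {
  structure(list(spectra = X, labels = labels,
                 provenance = data.frame(specimen = "toy",
                                         row = seq_len(nrow(X)),
                                         col = seq_len(nrow(X))),
                 wavelengths = seq_len(ncol(X)), seed = 1L),
            class = "training_set")
}
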