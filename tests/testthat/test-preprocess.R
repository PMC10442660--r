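test_that("reflectance calibration matches the defining arithmetic", {
  cal <- toy_calibration(ir = 500, iw = 900, id = 100)
  r <- compute_reflectance(cal)
  expect_true(all(r$data == 0.5))
  expect_equal(r$value_kind, "reflectance")
  # identity cases: Ir = Iw -> 1, Ir = Id -> 0
  expect_true(all(compute_reflectance(
    toy_calibration(900, 900, 100))$data == 1))
  expect_true(all(compute_reflectance(
    toy_calibration(100, 900, 100))$data == 0))
})

test_that("degenerate white = dark pixels are flagged, not an exception", {
  wl <- c(1000, 1100, 1300)
  iw <- array(900, c(2, 2, 3)); iw[1, 1, ] <- 100  # dead pixel
  cal <- calibration_set(hsi_cube(array(500, c(2, 2, 3)), wl, "raw"),
                         hsi_cube(iw, wl, "raw"),
                         hsi_cube(array(100, c(2, 2, 3)), wl, "raw"))
  r <- expect_no_error(compute_reflectance(cal))
  expect_true(all(is.finite(r$data)))
  flagged <- attr(r, "flagged")
  expect_identical(flagged, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
})

test_that("absorbance is -log10 of reflectance with a guarded floor", {
  expect_equal(as.vector(compute_absorbance(
    toy_calibration(500, 900, 100))$data[1, 1, ]),
    rep(log10(2), 4), tolerance = 1e-12)
  expect_true(all(compute_absorbance(toy_calibration(900, 900, 100))$data == 0))
  expect_equal(compute_absorbance(toy_calibration(108, 900, 100))$data[1, 1, 1],
               2, tolerance = 1e-12)  # R = 0.01 -> A = 2
  # order equivalence: -log10(R) == A wherever R is above the floor
  s <- small_specimen(seed = 21)
  r <- compute_reflectance(s$calibration)
  a <- compute_absorbance(s$calibration)
  ok <- r$data > 1e-6
  expect_equal(-log10(r$data[ok]), a$data[ok], tolerance = 1e-9)
})

test_that("SNV yields unit moments, affine invariance and idempotence", {
  wl3 <- c(1000, 1100, 1200)
  cube <- hsi_cube(array(c(1, 2, 3), c(1, 1, 3)), wl3, "absorbance")
  expect_equal(as.vector(snv_transform(cube)$data), c(-1, 0, 1))
  # affine invariance: a*x + b (a > 0) maps to the same output
  set.seed(1)
  wl64 <- wavelength_grid(to = 1400)
  x <- rnorm(64)
  c1 <- hsi_cube(array(x, c(1, 1, 64)), wl64, "absorbance")
  c2 <- hsi_cube(array(3.7 * x + 11, c(1, 1, 64)), wl64, "absorbance")
  expect_equal(snv_transform(c1)$data, snv_transform(c2)$data,
               tolerance = 1e-12)
  # moments on a random 64-band spectrum
  z <- as.vector(snv_transform(c1)$data)
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(stats::sd(z) - 1), 1e-9)
  # idempotence: SNV of an SNV spectrum is itself
  expect_equal(snv_transform(snv_transform(c1))$data,
               snv_transform(c1)$data, tolerance = 1e-12)
  # constant spectrum: flagged, zeroed, no exception
  cflat <- hsi_cube(array(5, c(1, 1, 3)), wl3, "absorbance")
  zf <- expect_no_error(snv_transform(cflat))
  expect_true(all(zf$data == 0))
  expect_true(attr(zf, "flagged")[1, 1])
})

test_that("wavelength trimming keeps exactly the in-window bands", {
  wl <- wavelength_grid()
  cube <- hsi_cube(array(1, c(2, 2, length(wl))), wl, "raw")
  trimmed <- trim_wavelengths(cube, c(1000, 1400))
  # oracle: enumerate grid points inside the window
  expect_equal(trimmed$wavelengths, wl[wl >= 1000 & wl <= 1400])
  expect_equal(n_bands(trimmed), 64L)
  expect_equal(max(trimmed$wavelengths), 1000 + 63 * 6.3)  # 1396.9 nm
  all_in <- trim_wavelengths(cube, c(900, 2400))
  expect_identical(all_in$data, cube$data)
  expect_error(trim_wavelengths(cube, c(500, 900)), "no bands")
})

test_that("Chebyshev dilation of one pixel at margin 5 covers 121 pixels", {
  got <- dilate_chebyshev(cbind(10L, 10L), 5L, c(30L, 30L))
  # brute-force oracle over every pixel
  oracle <- matrix(FALSE, 30, 30)
  for (r in 1:30) for (c_ in 1:30)
    oracle[r, c_] <- max(abs(r - 10), abs(c_ - 10)) <= 5
  expect_identical(got, oracle)
  expect_equal(sum(got), 121L)
  # clipping at the raster edge
  expect_equal(sum(dilate_chebyshev(cbind(1L, 1L), 5L, c(30L, 30L))), 36L)
})

test_that("validity mask applies thresholds, labels and precedence", {
  wl <- c(1290, 1300, 1310)
  r <- array(0.5, c(7, 7, 3))
  r[1, 1, 2] <- 0.75   # highlight at the 1300 nm band
  r[1, 2, 2] <- 0.05   # shadow
  r[1, 3, 2] <- 0.75   # highlight, but also necrosis -> necrosis wins
  labels <- matrix(LABELS[["normal"]], 7, 7)
  labels[1, 3] <- LABELS[["necrosis"]]
  labels[7, 7] <- LABELS[["outside_evaluated"]]
  labels[4, 4] <- LABELS[["exposed_tumor"]]
  th <- matrix(0, 7, 7); th[4, 4] <- 3
  ann <- annotation_map(labels, tumor_boundary = cbind(4L, 4L),
                        thickness_mm = th)
  cube <- hsi_cube(r, wl, "reflectance")
  m <- build_validity_mask(cube, ann, preprocess_params(margin_px = 2L))
  expect_equal(m$exclusion_reason[1, 1], "highlight")
  expect_equal(m$exclusion_reason[1, 2], "shadow")
  expect_equal(m$exclusion_reason[1, 3], "necrosis")
  expect_equal(m$exclusion_reason[7, 7], "outside_evaluated")
  expect_equal(m$exclusion_reason[4, 5], "boundary_margin")
  expect_equal(m$exclusion_reason[3, 3], "boundary_margin")
  expect_true(m$valid[7, 1])
  # margin 2 around (4,4): 5x5 square, minus nothing else overlapping
  expect_equal(sum(m$exclusion_reason == "boundary_margin", na.rm = TRUE), 25L)
})

test_that("growing the margin never revalidates a pixel", {
  s <- small_specimen(seed = 22)
  refl <- trim_wavelengths(compute_reflectance(s$calibration), c(1000, 1400))
  prev <- NULL
  for (m in c(0L, 2L, 5L, 8L)) {
    msk <- build_validity_mask(refl, s$annotation,
                               preprocess_params(margin_px = m))
    if (!is.null(prev)) expect_true(all(msk$valid <= prev))
    prev <- msk$valid
  }
})

test_that("preprocess_specimen assembles a consistent result", {
  s <- small_specimen(seed = 23)
  p <- preprocess_specimen(s)
  expect_s3_class(p, "preprocessed_specimen")
  expect_equal(p$snv$value_kind, "snv")
  expect_equal(n_bands(p$snv), 64L)
  expect_identical(dim(p$mask$valid), dim(s$annotation$labels))
  # every valid pixel's SNV spectrum has unit moments
  idx <- which(p$mask$valid)[1:20]
  d <- dim(p$snv$data)
  x <- matrix(p$snv$data, d[1] * d[2], d[3])[idx, ]
  expect_true(all(abs(rowMeans(x)) < 1e-9))
  expect_true(all(abs(apply(x, 1, stats::sd) - 1) < 1e-9))
})
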