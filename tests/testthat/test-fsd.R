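test_that("near-zero width deconvolution is the identity", {
  s <- lorentzianSpectrum(300, 40)
  out <- fsdTransform(s, fsdParams(1e-6, "boxcar", 1))
  expect_equal(absorbance(out), absorbance(s), tolerance = 1e-6)
})

test_that("deconvolving a Lorentzian narrows and heightens the band", {
  s <- lorentzianSpectrum(300, 40)
  d <- fsdTransform(s, fsdParams(30))
  expect_lt(measuredFwhm(d), 40)
  expect_gt(max(absorbance(d)), max(absorbance(s)))
})

test_that("narrowing is monotone in the deconvolution width", {
  s <- lorentzianSpectrum(300, 40)
  widths <- vapply(c(5, 10, 15, 20, 25, 30), function(w)
    measuredFwhm(fsdTransform(s, fsdParams(w))), numeric(1))
  expect_true(all(diff(widths) <= 1e-9))
})

test_that("a merged band pair is resolved into two maxima", {
  g <- fineGrid()
  l <- wavelengths(g)
  merged <- spectrum(g, 1 / (1 + (2 * (l - 292.5) / 30)^2) +
                        1 / (1 + (2 * (l - 307.5) / 30)^2))
  expect_equal(length(majorMaxima(merged)), 1L)
  split <- fsdTransform(merged, fsdParams(25))
  expect_equal(length(majorMaxima(split)), 2L)
})

test_that("the transform is linear and preserves the zeroth moment", {
  s1 <- lorentzianSpectrum(300, 40)
  s2 <- lorentzianSpectrum(250, 25)
  p <- fsdParams(20)
  lhs <- fsdTransform(spectrum(s1@grid,
                               2 * absorbance(s1) + 3 * absorbance(s2)), p)
  rhs <- 2 * absorbance(fsdTransform(s1, p)) +
         3 * absorbance(fsdTransform(s2, p))
  expect_equal(absorbance(lhs), rhs, tolerance = 1e-8)
  d <- fsdTransform(lorentzianSpectrum(300, 20),
                    fsdParams(15, "boxcar", 0.02, pad_factor = 1))
  expect_equal(sum(absorbance(d)) / sum(absorbance(lorentzianSpectrum(300, 20))),
               1, tolerance = 0.01)
})

test_that("overflowing amplification is caught with advice", {
  s <- lorentzianSpectrum(300, 40)
  expect_error(fsdTransform(s, fsdParams(100, "boxcar", 1)),
               "reduce fwhm_nm or apod_fraction")
  expect_error(fsdTransform(s, fsdParams(500)), "smaller than the spectral span")
})

test_that("zero-crossing search honors its contract", {
  g <- wavelengthGrid(240, 0.5, end_nm = 340)
  zero_set <- spectrumSet(matrix(0, nPoints(wavelengthGrid(240, 0.5, end_nm = 340)), 3),
                          grid = g)
  p <- fsdParams(10)
  zc <- findZeroCrossings(zero_set, p, tol = 1e-6)
  # every non-edge wavelength qualifies for an all-zero interferent
  expect_equal(length(zc), sum(!edgeMask(nPoints(g))))
  # strict zero tolerance on noisy spectra finds nothing
  noisy <- makeCalibrationSet(orLikeModel(), c(3, 10, 25),
                              noiseModel(0.002, 0, 1), scanGrid())
  expect_length(findZeroCrossings(noisy, p, tol = 0), 0)
  expect_error(findZeroCrossings(spectrumSet(matrix(0, 201, 2), grid = g), p),
               ">= 3")
})

test_that("found crossings are self-consistent on an interferent set", {
  it <- makeCalibrationSet(orLikeModel(), c(3, 10, 25), NULL, scanGrid())
  p <- fsdParams(30)
  tol <- 2e-3
  zc <- findZeroCrossings(it, p, tol)
  expect_gt(length(zc), 0)
  dec <- vapply(1:3, function(i)
    absorbance(fsdTransform(getSpectrum(it, i), p)), numeric(2001))
  idx <- gridIndex(scanGrid(), zc)
  expect_true(all(apply(abs(dec[idx, , drop = FALSE]), 1, max) < tol))
})

test_that("zero-crossing calibration is linear and guarded", {
  an <- makeCalibrationSet(ciLikeModel(), c(2, 4, 6, 8, 10, 12, 15), NULL,
                           scanGrid())
  cal <- calibrateFsd(an, 279.3, fsdParams(30))
  expect_gt(cal@fit@r_squared, 0.9999)
  one <- makeCalibrationSet(ciLikeModel(), c(5, 5, 5), NULL, scanGrid())
  expect_error(calibrateFsd(one, 279.3, fsdParams(30)), "degenerate")
})

test_that("prediction at a zero crossing rejects the interferent", {
  sg <- scanGrid()
  an <- makeCalibrationSet(ciLikeModel(), c(2, 4, 6, 8, 10, 12, 15), NULL, sg)
  it <- makeCalibrationSet(orLikeModel(), c(3, 10, 25), NULL, sg)
  sel <- selectFsdFwhm(an, it, tol = 2e-3)
  expect_false(is.null(sel))
  cal <- calibrateFsd(an, sel$wavelength_nm, sel$params)
  comps <- defaultComponents()
  # interferent-only mixture predicts ~0 analyte
  pure_or <- mixSpectra(comps, c(0, 20), NULL, sg)
  expect_lt(abs(predictFsd(pure_or, cal)), 0.05)
  # noiseless round trip at c = 8 within 2%
  mx <- mixSpectra(comps, c(8, 12), NULL, sg)
  expect_equal(predictFsd(mx, cal), 8, tolerance = 0.02)
  wrong <- mixSpectra(comps, c(8, 12), NULL,
                      wavelengthGrid(200, 0.5, end_nm = 400))
  expect_error(predictFsd(wrong, cal), "mismatch")
})

test_that("the analytic noise gain tracks a Monte Carlo estimate", {
  # the kernel formula ignores the correlations the even-symmetric
  # extension introduces, so it is an order estimate: require agreement
  # within ~50%, which is ample for a 3-sigma crossing threshold
  g <- wavelengthGrid(240, 0.1, end_nm = 340)
  p <- fsdParams(20)
  gain <- fsdNoiseGain(g, p)
  set.seed(3)
  sds <- replicate(20, {
    n <- spectrum(g, rnorm(nPoints(g), 0, 0.01))
    stats::sd(absorbance(fsdTransform(n, p)))
  })
  ratio <- (mean(sds) / 0.01) / gain
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.6)
})
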