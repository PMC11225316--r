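test_that("mean centering matches the worked example and its identities", {
  expect_equal(meanCenter(c(3, 6, 3)), c(-1, 2, -1))
  expect_equal(mean(meanCenter(c(3, 6, 3))), 0)
  expect_equal(meanCenter(rep(4.2, 7)), rep(0, 7))
  v <- c(1.3, -2, 5, 0.1)
  expect_equal(meanCenter(meanCenter(v)), meanCenter(v))
  expect_lt(abs(sum(meanCenter(rnorm(50)))), 1e-12)
  expect_error(meanCenter(3), "at least 2")
})

test_that("the pipeline annihilates the divisor component", {
  sg <- scanGrid()
  comps <- defaultComponents()
  or20 <- mixSpectra(comps, c(0, 20), NULL, sg)
  # mixture containing only the divisor's component, any concentration
  for (k in c(3, 12, 25)) {
    mx <- mixSpectra(comps, c(0, k), NULL, sg)
    out <- mcPipeline(mx, or20, c(260, 340))
    expect_lt(max(abs(absorbance(out)), na.rm = TRUE), 1e-10)
  }
  # analyte-only mixture: output linear in analyte concentration
  a1 <- mcPipeline(mixSpectra(comps, c(2, 0), NULL, sg), or20, c(240, 290))
  a3 <- mcPipeline(mixSpectra(comps, c(6, 0), NULL, sg), or20, c(240, 290))
  expect_equal(absorbance(a3), 3 * absorbance(a1), tolerance = 1e-10)
})

test_that("masked points are excluded from the centering mean", {
  g <- wavelengthGrid(240, 0.5, end_nm = 340)
  num <- spectrum(g, rep(1, nPoints(g)))
  den <- spectrum(g, rep(c(1, 1e-6), length.out = nPoints(g)))
  out <- mcPipeline(num, den, c(250, 330), floor = 1e-3)
  expect_true(any(is.na(absorbance(out))))
  expect_equal(mean(absorbance(out), na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("mean-centering calibration is linear and elects a maximum", {
  sg <- scanGrid()
  an <- makeCalibrationSet(ciLikeModel(), c(2, 4, 6, 8, 10, 12, 15), NULL, sg)
  div <- getSpectrum(makeCalibrationSet(orLikeModel(), 20, NULL, sg), 1)
  cal <- calibrateMc(an, div, 20, c(240, 290))
  expect_gt(cal@fit@r_squared, 0.9999)
  expect_true(cal@lambda_max_nm >= 240 && cal@lambda_max_nm <= 290)
  one <- makeCalibrationSet(ciLikeModel(), c(5, 5), NULL, sg)
  expect_error(calibrateMc(one, div, 20, c(240, 290)), "degenerate")
})

test_that("prediction recovers concentrations and rejects the interferent", {
  sg <- scanGrid()
  comps <- defaultComponents()
  an <- makeCalibrationSet(ciLikeModel(), c(2, 4, 6, 8, 10, 12, 15), NULL, sg)
  div <- getSpectrum(makeCalibrationSet(orLikeModel(), 20, NULL, sg), 1)
  cal <- calibrateMc(an, div, 20, c(240, 290))
  # analyte-free mixture predicts ~0
  expect_lt(abs(predictMc(mixSpectra(comps, c(0, 15), NULL, sg), cal)), 0.05)
  # c = 10 round trip within 2% under default noise
  mx <- mixSpectra(comps, c(10, 12), noiseModel(seed = 8), sg)
  expect_equal(predictMc(mx, cal), 10, tolerance = 0.02)
  expect_error(predictMc(mixSpectra(comps, c(1, 1), NULL,
                                    wavelengthGrid(200, 0.5, end_nm = 400)),
                         cal), "mismatch")
})

test_that("divisor concentration cancels so selection ties break low", {
  sg <- scanGrid()
  an <- makeCalibrationSet(ciLikeModel(), c(2, 6, 10, 15), NULL, sg)
  cands <- makeCalibrationSet(orLikeModel(), c(5, 10, 20), NULL, sg)
  vmix <- makeMixtureSet(defaultComponents(),
                         rbind(c(10, 5), c(5, 15), c(3, 10)), NULL, sg)
  sel <- selectDivisor(cands, an, vmix, c(240, 290))
  expect_equal(sel$divisor_conc, 5)      # noiseless: all tie, lowest wins
  expect_lt(sel$loss, 0.01)
  # selection is deterministic for a fixed noise seed
  noisy_cands <- makeCalibrationSet(orLikeModel(), c(5, 10, 20),
                                    noiseModel(seed = 2), sg)
  s1 <- selectDivisor(noisy_cands, an, vmix, c(240, 290))
  s2 <- selectDivisor(noisy_cands, an, vmix, c(240, 290))
  expect_identical(s1$divisor_conc, s2$divisor_conc)
})

test_that("range election reports every candidate and finds a built winner", {
  sg <- scanGrid()
  an <- makeCalibrationSet(ciLikeModel(), c(2, 6, 10, 15), NULL, sg)
  div <- getSpectrum(makeCalibrationSet(orLikeModel(), 20, NULL, sg), 1)
  vmix <- makeMixtureSet(defaultComponents(),
                         rbind(c(10, 5), c(5, 15), c(3, 10)),
                         noiseModel(seed = 3), sg)
  ranges <- defaultMcRanges("CI")
  sel <- selectRange(ranges, an, vmix, div, 20)
  expect_equal(nrow(sel$report), length(ranges))
  expect_true(all(c("slope", "intercept", "loss", "recovery_mix1") %in%
                  names(sel$report)))
  expect_true(list(sel$range_nm) %in% lapply(ranges, as.numeric) ||
              any(vapply(ranges, function(r) all(r == sel$range_nm), logical(1))))
  # single candidate comes straight back
  one <- selectRange(list(c(240, 290)), an, vmix, div, 20)
  expect_equal(one$range_nm, c(240, 290))
})
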