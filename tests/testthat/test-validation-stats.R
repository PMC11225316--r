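test_that("straight-line fitting matches the normal-equation oracle", {
  f <- fitLinear(c(1, 2, 3), c(3, 5, 7))
  expect_equal(f@slope, 2)
  expect_equal(f@intercept, 1)
  expect_equal(f@r_squared, 1)
  # two points always saturate
  expect_equal(fitLinear(c(1, 4), c(2, -1))@r_squared, 1)
  set.seed(21)
  x <- rnorm(10); y <- 2 * x + rnorm(10)
  f2 <- fitLinear(x, y)
  lmfit <- stats::lm(y ~ x)
  expect_equal(f2@slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(f2@intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(f2@residual_sd, summary(lmfit)$sigma, tolerance = 1e-10)
  expect_equal(f2@r_squared, summary(lmfit)$r.squared, tolerance = 1e-10)
  expect_error(fitLinear(c(2, 2, 2), c(1, 2, 3)), "degenerate")
})

test_that("prediction-error metrics evaluate their printed formulas", {
  expect_equal(msep(c(1, 2), c(1, 2)), 0)
  expect_equal(bcmsep(c(1, 2), c(1, 2)), 0)
  # hand evaluation: d = (0.1, -0.1)
  expect_equal(msep(c(1, 2), c(1.1, 1.9)), 0.01)
  expect_equal(rrmsep(c(1, 2), c(1.1, 1.9)), (100 / 1.5) * 0.1)
  # constant bias: corrected form is blind to it, msep is not
  ct <- c(1, 2, 3, 4); cp <- ct + 0.5
  expect_equal(bcmsep(ct, cp), 0)
  expect_equal(msep(ct, cp), 0.25)
  # the printed formula collapses algebraically to msep
  set.seed(2); a <- runif(8); b <- runif(8)
  expect_equal(bcmsep(a, b, form = "printed"), msep(a, b), tolerance = 1e-12)
  # corrected form bounded by n/(n-1) msep, equality iff zero-mean error
  for (i in 1:20) {
    ct <- runif(6, 1, 10); cp <- ct + rnorm(6, 0, 0.3)
    n <- 6
    expect_lte(bcmsep(ct, cp), n / (n - 1) * msep(ct, cp) + 1e-12)
  }
  d0 <- c(-0.2, 0.1, 0.1)   # zero-mean errors: equality case
  expect_equal(bcmsep(c(1, 2, 3), c(1, 2, 3) + d0),
               3 / 2 * msep(c(1, 2, 3), c(1, 2, 3) + d0))
  expect_equal(sqrt(msep(a, b)), predictionMetrics(a, b)$rmse)
})

test_that("recovery excludes undefined zero-truth samples", {
  r <- recoveryStats(c(0, 2, 4), c(0.1, 2.1, 3.8))
  expect_true(is.na(r$recoveries[1]))
  expect_equal(r$n_defined, 2L)
  expect_equal(r$mean_recovery, mean(c(105, 95)))
  allzero <- recoveryStats(c(0, 0), c(0.1, -0.1))
  expect_true(is.na(allzero$mean_recovery))
  expect_equal(allzero$n_defined, 0L)
})

test_that("detection limits follow the 3.3/10 sigma convention", {
  f <- new("LinearFit", slope = 0.2732, intercept = 0.0031,
           r_squared = 0.9999, residual_sd = 0.00886, n = 7L)
  dlql <- detectionLimits(f)
  expect_equal(dlql$ql / dlql$dl, 10 / 3.3)
  # a residual sd giving the published DL pairs with a QL at ~3.03x
  expect_equal(dlql$dl, 3.3 * 0.00886 / 0.2732)
  fz <- new("LinearFit", slope = 2, intercept = 0, r_squared = 1,
            residual_sd = 0, n = 5L)
  expect_equal(unlist(detectionLimits(fz)), c(dl = 0, ql = 0))
  f0 <- new("LinearFit", slope = 1, intercept = 0, r_squared = 1,
            residual_sd = 1, n = 5L)
  f0@slope <- 0
  expect_error(detectionLimits(f0), "zero slope")
})

test_that("rsd and standard addition compute as defined", {
  expect_equal(rsd(c(9, 10, 11)), 100 * sd(c(9, 10, 11)) / 10)
  sa <- standardAddition(5, c(4, 5, 6), c(9.1, 9.9, 11.1))
  expect_equal(sa$recoveries, c(102.5, 98, 101 + 2 / 3), tolerance = 1e-10)
})

test_that("two-sample t and variance-ratio F match hand formulas", {
  tt <- twoSampleT(10, 1, 5, 10, 2, 5)
  expect_equal(tt$t, 0)
  expect_equal(tt$df, 8)
  expect_equal(tt$t_crit, 2.306, tolerance = 1e-3)
  # oracle: pooled formula by hand
  t2 <- twoSampleT(100.57, 0.86, 5, 100.16, 1.82, 5)
  sp2 <- (4 * 0.86^2 + 4 * 1.82^2) / 8
  expect_equal(t2$t, (100.57 - 100.16) / sqrt(sp2 * 0.4), tolerance = 1e-12)
  ff <- varianceRatioF(2, 5, 2, 5)
  expect_equal(ff$f, 1)
  expect_equal(ff$f_crit, 6.388, tolerance = 1e-4)
  f2 <- varianceRatioF(0.7378, 5, 3.3282, 5)
  expect_equal(f2$f, 3.3282 / 0.7378)
  expect_equal(f2$df1, 4)
})

test_that("one-way ANOVA agrees between raw and summary entry points", {
  set.seed(31)
  groups <- replicate(4, rnorm(5, 10, 1.5), simplify = FALSE)
  a_raw <- anovaOneway(groups = groups)
  a_sum <- anovaOneway(ss_between = a_raw$ss_between, df_between = 3,
                       ss_within = a_raw$ss_within, df_within = 16)
  expect_equal(a_raw$f_value, a_sum$f_value, tolerance = 1e-10)
  # brute-force decomposition oracle
  all <- unlist(groups)
  sst <- sum((all - mean(all))^2)
  expect_equal(a_raw$ss_between + a_raw$ss_within, sst, tolerance = 1e-10)
  aovfit <- summary(stats::aov(all ~ factor(rep(1:4, each = 5))))[[1]]
  expect_equal(a_raw$f_value, aovfit$`F value`[1], tolerance = 1e-8)
  expect_equal(a_raw$p_value, aovfit$`Pr(>F)`[1], tolerance = 1e-8)
  # equal group means give F ~ 0
  eq <- anovaOneway(groups = list(c(1, 2, 3), c(2, 1, 3), c(3, 2, 1)))
  expect_equal(eq$f_value, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)
})

test_that("critical values reproduce the quoted table constants", {
  expect_equal(fCritical(0.05, 3, 16), 3.238872, tolerance = 1e-6)
  expect_equal(tCritical(0.05, 8), 2.306, tolerance = 1e-3)
  expect_equal(fCritical(0.05, 4, 4), 6.388, tolerance = 1e-4)
  expect_equal(tCritical(1, 10), 0)
})
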