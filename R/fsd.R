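#' Fourier self-deconvolution parameters
#'
#' @param fwhm_nm assumed Lorentzian width of the broadening to remove (nm)
#' @param apodization tapering window applied to the interferogram:
#'   "triangular_sq" (default), "boxcar", "triangular" or "bessel_like"
#' @param apod_fraction fraction (0, 1] of the interferogram retained; the
#'   window support ends at \code{apod_fraction} of the Nyquist abscissa
#' @param pad_factor integer >= 1; the spectrum is padded at both ends with
#'   its edge values to \code{pad_factor} times its length before the
#'   even-symmetric extension, suppressing wrap-around
#' @param width_convention "fwhm" (default) or "hwhm"; see
#'   \linkS4class{FsdParams}
#' @return an \linkS4class{FsdParams}
#' @export
fsdParams <- function(fwhm_nm, apodization = "triangular_sq",
                      apod_fraction = 0.02, pad_factor = 2L,
                      width_convention = "fwhm") {
  new("FsdParams", fwhm_nm = as.numeric(fwhm_nm),
      apodization = apodization, apod_fraction = as.numeric(apod_fraction),
      pad_factor = as.integer(pad_factor),
      width_convention = width_convention)
}

apodWindow <- function(type, x, L) {
  u <- x / L
  w <- switch(type,
    boxcar = rep(1, length(u)),
    triangular = 1 - u,
    triangular_sq = (1 - u)^2,
    bessel_like = (1 - u^2)^2,
    stop("unknown apodization: ", type))
  w[u > 1] <- 0
  w[w < 0] <- 0
  w
}

#' Fourier self-deconvolution of a spectrum
#'
#' Classical Kauppinen-style self-deconvolution: the spectrum is padded and
#' even-symmetrically extended, carried to the interferogram domain by FFT,
#' multiplied by exp(pi * w * |x|) (cancelling the Fourier decay of an
#' assumed Lorentzian broadening of FWHM w) times the tapering window, and
#' transformed back. Bands narrower than the assumed width sharpen; the
#' zeroth moment is preserved (the window is 1 at x = 0).
#'
#' The first and last 5\% of points are edge-affected
#' (see \code{\link{edgeMask}}).
#'
#' @param s a \linkS4class{Spectrum} without masked points
#' @param p an \linkS4class{FsdParams}
#' @return the deconvolved \linkS4class{Spectrum} on the same grid
#' @export
fsdTransform <- function(s, p) {
  if (anyNA(s@absorbance)) stop("cannot deconvolve a spectrum with masked points")
  y <- s@absorbance
  N <- length(y)
  d <- s@grid@step_nm
  if (p@fwhm_nm >= (gridEnd(s@grid) - s@grid@start_nm))
    stop("fwhm_nm must be smaller than the spectral span")
  npad <- as.integer(ceiling((p@pad_factor - 1L) * N / 2))
  v <- c(rep(y[1], npad), y, rep(y[N], npad))
  Np <- length(v)
  ext <- c(v, rev(v[2:(Np - 1L)]))
  M <- length(ext)
  k <- 0:(M - 1L)
  x <- pmin(k, M - k) / (M * d)           # cycles per nm
  xmax <- 1 / (2 * d)
  L <- p@apod_fraction * xmax
  sigma <- if (p@width_convention == "fwhm") p@fwhm_nm else 2 * p@fwhm_nm
  if (pi * sigma * min(L, xmax) > 700)
    stop("exponential amplification overflows: reduce fwhm_nm or apod_fraction")
  K <- exp(pi * sigma * pmin(x, L)) * apodWindow(p@apodization, x, L)
  out <- Re(stats::fft(stats::fft(ext) * K, inverse = TRUE)) / M
  spectrum(s@grid, out[(npad + 1L):(npad + N)], s@label)
}

#' Edge-affected region of a deconvolved spectrum
#'
#' @param n number of grid points
#' @param frac fraction flagged at each end (default 5\%)
#' @return logical vector, TRUE where edge-affected
#' @export
edgeMask <- function(n, frac = 0.05) {
  ne <- ceiling(frac * n)
  i <- seq_len(n)
  i <= ne | i > n - ne
}

#' Robust photometric noise estimate
#'
#' Standard deviation of successive differences divided by sqrt(2); smooth
#' signal contributes little to first differences, so this estimates the
#' white-noise floor of a raw spectrum.
#'
#' @param s a \linkS4class{Spectrum}
#' @return estimated noise sd (AU)
#' @export
estimateNoiseSd <- function(s) {
  dy <- diff(s@absorbance[!is.na(s@absorbance)])
  stats::mad(dy) / sqrt(2)
}

#' Noise amplification factor of a deconvolution
#'
#' The transform is linear, so white photometric noise of sd s on the raw
#' spectrum leaves the deconvolved spectrum with (colored) noise of sd
#' approximately s * sqrt(mean(K^2)), K being the interferogram-domain
#' kernel (exponential amplification times the tapering window).
#'
#' @param grid the \linkS4class{WavelengthGrid} the transform will run on
#' @param p an \linkS4class{FsdParams}
#' @return the amplification factor sqrt(mean(K^2))
#' @export
fsdNoiseGain <- function(grid, p) {
  N <- grid@n_points
  d <- grid@step_nm
  npad <- as.integer(ceiling((p@pad_factor - 1L) * N / 2))
  M <- 2L * (N + 2L * npad) - 2L
  k <- 0:(M - 1L)
  x <- pmin(k, M - k) / (M * d)
  L <- p@apod_fraction / (2 * d)
  sigma <- if (p@width_convention == "fwhm") p@fwhm_nm else 2 * p@fwhm_nm
  if (pi * sigma * L > 700) return(Inf)
  K <- exp(pi * sigma * pmin(x, L)) * apodWindow(p@apodization, x, L)
  sqrt(mean(K^2))
}

#' Zero-crossing wavelengths of a deconvolved interferent
#'
#' Applies the deconvolution to every spectrum of the interferent set and
#' returns the wavelengths at which the deconvolved signal magnitude stays
#' below \code{tol} for all provided concentrations, so an analyte can be
#' read there free of interference. Edge-affected points are excluded.
#'
#' @param interferent_set \linkS4class{SpectrumSet} of the interfering
#'   component at three or more concentrations (raw spectra; the transform
#'   is applied internally)
#' @param p an \linkS4class{FsdParams}
#' @param tol signal magnitude threshold (AU); default three times the
#'   deconvolved noise floor, i.e. 3 * raw noise sd * kernel amplification
#'   (see \code{\link{fsdNoiseGain}})
#' @return sorted numeric vector of wavelengths (nm); may be empty
#' @export
findZeroCrossings <- function(interferent_set, p, tol = NULL) {
  ns <- nSpectra(interferent_set)
  if (ns < 3L)
    stop("need interferent spectra at >= 3 concentrations")
  dec <- vapply(seq_len(ns),
                function(i) fsdTransform(getSpectrum(interferent_set, i), p)@absorbance,
                numeric(nPoints(interferent_set)))
  if (is.null(tol)) {
    raw_sd <- max(vapply(seq_len(ns), function(i)
      estimateNoiseSd(getSpectrum(interferent_set, i)), numeric(1)))
    tol <- 3 * raw_sd * fsdNoiseGain(interferent_set@grid, p)
  }
  if (tol <= 0) return(numeric(0))
  maxabs <- apply(abs(dec), 1, max)
  ok <- maxabs < tol & !edgeMask(nrow(dec))
  sort(wavelengths(interferent_set)[ok])
}

#' Build a zero-crossing calibration
#'
#' Ordinary least squares of the deconvolved signal at the elected
#' wavelength against the analyte concentration.
#'
#' @param analyte_set \linkS4class{SpectrumSet} of the pure analyte with a
#'   1-column concentration matrix
#' @param wavelength_nm measurement wavelength (on the grid)
#' @param p an \linkS4class{FsdParams}
#' @return a \linkS4class{ZeroCrossingCalibration}
#' @export
calibrateFsd <- function(analyte_set, wavelength_nm, p) {
  conc <- analyteConcs(analyte_set)
  if (length(unique(conc)) < 2L)
    stop("degenerate design: need >= 2 distinct concentrations")
  idx <- gridIndex(analyte_set@grid, wavelength_nm)
  sig <- vapply(seq_len(nSpectra(analyte_set)), function(i)
    fsdTransform(getSpectrum(analyte_set, i), p)@absorbance[idx],
    numeric(1))
  fit <- fitLinear(conc, sig)
  new("ZeroCrossingCalibration",
      wavelength_nm = wavelengths(analyte_set)[idx], fit = fit,
      fsd_params = p, grid = analyte_set@grid)
}

analyteConcs <- function(set, component = 1L) {
  cc <- set@concentrations
  if (is.null(cc)) stop("spectrum set carries no concentrations")
  as.numeric(cc[, component])
}

#' Predict a concentration from a mixture by zero-crossing deconvolution
#'
#' @param mixture a \linkS4class{Spectrum} on the calibration grid
#' @param cal a \linkS4class{ZeroCrossingCalibration}
#' @return estimated concentration (ug/ml)
#' @export
predictFsd <- function(mixture, cal) {
  if (!sameGrid(mixture@grid, cal@grid))
    stop("grid mismatch: mixture is not on the calibration grid")
  dec <- fsdTransform(mixture, cal@fsd_params)
  idx <- gridIndex(cal@grid, cal@wavelength_nm)
  (dec@absorbance[idx] - cal@fit@intercept) / cal@fit@slope
}

#' Grid-search election of the deconvolution width
#'
#' Reproduces the width-selection procedure: each candidate width is applied
#' to the interferent calibration spectra and its zero-crossing wavelengths
#' located. Crossing quality is the analyte's calibration-slope magnitude
#' there divided by the crossing tolerance — a signal-to-interference ratio
#' that penalizes over-deconvolved candidates whose amplified noise floor
#' admits spurious crossings. The width (and wavelength) with the best
#' usable crossing wins; widths with none are disqualified.
#'
#' @param analyte_set pure-analyte \linkS4class{SpectrumSet}
#' @param interferent_set pure-interferent \linkS4class{SpectrumSet}
#' @param fwhm_values candidate widths (nm)
#' @param base an \linkS4class{FsdParams} template supplying apodization,
#'   apod_fraction and pad_factor
#' @param tol zero-crossing threshold (AU); NULL for the automatic default
#' @param r2_min minimum calibration R-squared for a crossing to count
#' @return list(fwhm_nm, wavelength_nm, params, quality) or NULL when no
#'   candidate has a usable zero crossing
#' @export
selectFsdFwhm <- function(analyte_set, interferent_set,
                          fwhm_values = c(10, 30, 50, 70),
                          base = fsdParams(10), tol = NULL,
                          r2_min = 0.99) {
  best <- NULL
  conc <- analyteConcs(analyte_set)
  raw_sd <- max(vapply(seq_len(nSpectra(interferent_set)), function(i)
    estimateNoiseSd(getSpectrum(interferent_set, i)), numeric(1)))
  for (w in fwhm_values) {
    p <- fsdParams(w, base@apodization, base@apod_fraction,
                   base@pad_factor, base@width_convention)
    tol_w <- if (is.null(tol))
      3 * raw_sd * fsdNoiseGain(interferent_set@grid, p) else tol
    if (!is.finite(tol_w) || tol_w <= 0) next
    zc <- tryCatch(findZeroCrossings(interferent_set, p, tol_w),
                   error = function(e) numeric(0))
    if (!length(zc)) next
    dec <- vapply(seq_len(nSpectra(analyte_set)), function(i)
      fsdTransform(getSpectrum(analyte_set, i), p)@absorbance,
      numeric(nPoints(analyte_set)))
    idx <- gridIndex(analyte_set@grid, zc)
    fits <- lapply(idx, function(j) fitLinear(conc, dec[j, ]))
    slopes <- vapply(fits, function(f) f@slope, numeric(1))
    r2 <- vapply(fits, function(f) f@r_squared, numeric(1))
    usable <- r2 >= r2_min
    if (!any(usable)) next
    q_all <- abs(slopes) / tol_w
    q <- max(q_all[usable])
    if (is.null(best) || q > best$quality) {
      jbest <- which(usable)[which.max(q_all[usable])]
      best <- list(fwhm_nm = w, wavelength_nm = zc[jbest], params = p,
                   quality = q)
    }
  }
  best
}
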