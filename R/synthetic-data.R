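#' Evaluate with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so seeded generators never disturb a session.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spectral band definition
#'
#' A single absorption band of an analyte's unit-concentration spectrum.
#' Heights are absorptivities: AU per ug/ml at the band maximum.
#'
#' @param shape "gaussian", "lorentzian" or "pseudo_voigt"
#' @param center_nm band center (nm)
#' @param fwhm_nm full width at half maximum (nm), > 0
#' @param height peak absorptivity (AU ml/ug), > 0
#' @param eta Lorentzian fraction for pseudo_voigt, in [0, 1]
#' @return a "band" list
#' @export
band <- function(shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                 center_nm, fwhm_nm, height, eta = 0.5) {
  shape <- match.arg(shape)
  stopifnot(fwhm_nm > 0, height > 0, eta >= 0, eta <= 1)
  structure(list(shape = shape, center_nm = center_nm, fwhm_nm = fwhm_nm,
                 height = height, eta = eta), class = "band")
}

bandProfile <- function(b, lambda) {
  u <- 2 * (lambda - b$center_nm) / b$fwhm_nm
  gauss <- exp(-log(2) * u^2)
  lor <- 1 / (1 + u^2)
  b$height * switch(b$shape,
    gaussian = gauss,
    lorentzian = lor,
    pseudo_voigt = b$eta * lor + (1 - b$eta) * gauss)
}

#' Component model: a named sum of bands
#'
#' @param name component name
#' @param bands list of \code{\link{band}} objects
#' @return a "componentModel" list
#' @export
componentModel <- function(name, bands) {
  stopifnot(is.character(name), length(bands) >= 1)
  structure(list(name = name, bands = bands), class = "componentModel")
}

#' Unit-concentration spectrum of a component model
#'
#' @param m a \code{\link{componentModel}}
#' @param grid a \linkS4class{WavelengthGrid}
#' @return a \linkS4class{Spectrum} of the absorptivity a(lambda) (AU ml/ug)
#' @export
componentSpectrum <- function(m, grid) {
  lambda <- wavelengths(grid)
  y <- Reduce(`+`, lapply(m$bands, bandProfile, lambda = lambda))
  spectrum(grid, y, m$name)
}

#' Noise model for synthetic spectra
#'
#' Additive white photometric noise plus an optional slow degree-2
#' polynomial baseline drift. Identical seeds give bit-identical spectra.
#'
#' @param additive_sd photometric noise sd (AU), >= 0
#' @param baseline_amp bound on the drift polynomial coefficients (AU), >= 0
#' @param seed integer seed
#' @return a "noiseModel" list
#' @export
noiseModel <- function(additive_sd = 0.002, baseline_amp = 0, seed = 1L) {
  stopifnot(additive_sd >= 0, baseline_amp >= 0)
  structure(list(additive_sd = additive_sd, baseline_amp = baseline_amp,
                 seed = as.integer(seed)), class = "noiseModel")
}

noiseRealization <- function(noise, grid) {
  n <- grid@n_points
  eps <- if (noise$additive_sd > 0) stats::rnorm(n, 0, noise$additive_sd)
         else numeric(n)
  if (noise$baseline_amp > 0) {
    t <- seq(-1, 1, length.out = n)
    co <- stats::runif(3, -noise$baseline_amp, noise$baseline_amp)
    eps <- eps + co[1] + co[2] * t + co[3] * t^2
  }
  eps
}

#' Beer-Lambert mixture spectrum
#'
#' A(lambda) = sum_i a_i(lambda) c_i + baseline + noise. With the noise
#' model absent (or zero sd and amplitude) the output is exactly the linear
#' combination.
#'
#' @param components list of \code{\link{componentModel}}
#' @param conc concentrations (ug/ml), one per component, >= 0
#' @param noise a \code{\link{noiseModel}} or NULL for noiseless
#' @param grid a \linkS4class{WavelengthGrid}
#' @param label spectrum label
#' @return a \linkS4class{Spectrum}
#' @export
mixSpectra <- function(components, conc, noise = NULL, grid,
                       label = "mixture") {
  if (length(components) != length(conc))
    stop("components and conc lengths differ")
  if (any(conc < 0)) stop("negative concentration")
  lambda <- wavelengths(grid)
  y <- numeric(grid@n_points)
  for (i in seq_along(components))
    if (conc[i] > 0)
      y <- y + conc[i] * componentSpectrum(components[[i]], grid)@absorbance
  if (!is.null(noise))
    y <- y + withSeed(noise$seed, noiseRealization(noise, grid))
  spectrum(grid, y, label)
}

#' Generate a spectrum set from a concentration design
#'
#' One mixture spectrum per design row, with independent noise per sample
#' drawn from a single seeded stream (same seed, same set).
#'
#' @param components list of \code{\link{componentModel}}
#' @param design samples x components concentration matrix (ug/ml)
#' @param noise a \code{\link{noiseModel}} or NULL
#' @param grid a \linkS4class{WavelengthGrid}
#' @return a \linkS4class{SpectrumSet} with concentrations recorded
#' @export
makeMixtureSet <- function(components, design, noise = NULL, grid) {
  design <- as.matrix(design)
  if (ncol(design) != length(components))
    stop("design columns must match number of components")
  pure <- vapply(components, function(m) componentSpectrum(m, grid)@absorbance,
                 numeric(grid@n_points))
  base <- pure %*% t(design)
  if (!is.null(noise)) {
    eps <- withSeed(noise$seed, vapply(seq_len(nrow(design)), function(i)
      noiseRealization(noise, grid), numeric(grid@n_points)))
    base <- base + eps
  }
  colnames(base) <- paste0("mix", seq_len(nrow(design)))
  colnames(design) <- vapply(components, function(m) m$name, character(1))
  spectrumSet(base, concentrations = design, grid = grid)
}

#' Single-component calibration set
#'
#' @param component a \code{\link{componentModel}}
#' @param conc_list concentrations (ug/ml)
#' @param noise a \code{\link{noiseModel}} or NULL
#' @param grid a \linkS4class{WavelengthGrid}
#' @return a \linkS4class{SpectrumSet} with a 1-column concentration matrix
#' @export
makeCalibrationSet <- function(component, conc_list, noise = NULL, grid) {
  makeMixtureSet(list(component), matrix(conc_list, ncol = 1), noise, grid)
}

#' Default ciprofloxacin-like component model
#'
#' Strong band near 277 nm with a weak long-wave shoulder near 315 nm;
#' heights sized so the 2-15 ug/ml working range stays within ~1.2 AU.
#' @return a \code{\link{componentModel}}
#' @export
ciLikeModel <- function() {
  componentModel("CI", list(
    band("gaussian", center_nm = 277, fwhm_nm = 28, height = 0.075),
    band("gaussian", center_nm = 313, fwhm_nm = 20, height = 0.025)))
}

#' Default ornidazole-like component model
#'
#' Broad band near 312 nm plus a rising short-wave band below 240 nm,
#' overlapping the ciprofloxacin-like band strongly enough that neither
#' component has an interference-free wavelength in the raw spectra.
#' @return a \code{\link{componentModel}}
#' @export
orLikeModel <- function() {
  componentModel("OR", list(
    band("gaussian", center_nm = 308, fwhm_nm = 45, height = 0.035),
    band("gaussian", center_nm = 228, fwhm_nm = 42, height = 0.055)))
}

#' Full-resolution scan grid (200-400 nm, 0.1 nm)
#' @return a \linkS4class{WavelengthGrid}
#' @export
scanGrid <- function() wavelengthGrid(200, 0.1, end_nm = 400)

#' Neural-input grid (279.0-316.0 nm, 0.5 nm; 75 points)
#' @return a \linkS4class{WavelengthGrid}
#' @export
annGrid <- function() wavelengthGrid(279, 0.5, end_nm = 316)

#' Published 32-mixture training design
#'
#' The two-component training concentrations (ug/ml): CI 2-15, OR 0-25.
#' @return 32 x 2 matrix with columns CI, OR
#' @export
referenceTrainingDesign <- function() {
  m <- matrix(c(
     2.0,  3.0,   3.0,  5.0,   5.0, 10.0,   8.0, 15.0,
     2.5, 10.0,   2.0,  5.0,   5.0, 15.0,   3.0,  3.0,
     5.0,  5.0,   8.0, 10.0,  10.0,  3.0,  15.0,  0.0,
     3.0, 10.0,   2.0, 10.0,   3.0, 15.0,   5.0, 20.0,
     8.0, 25.0,   3.0, 10.0,   5.0, 15.0,   2.0, 20.0,
     3.0, 25.0,   5.0, 15.0,   8.0, 15.0,  10.0,  5.0,
     2.0, 15.0,   3.0, 10.0,   5.0, 15.0,   8.0, 20.0,
     2.0, 25.0,   3.0,  3.0,   5.0, 25.0,   8.0,  3.0),
    ncol = 2, byrow = TRUE)
  colnames(m) <- c("CI", "OR")
  m
}

#' Published 10-mixture test design
#'
#' The two-component test concentrations (ug/ml) used to judge the trained
#' networks; the first mixture contains no CI.
#' @return 10 x 2 matrix with columns CI, OR
#' @export
referenceTestDesign <- function() {
  m <- matrix(c(
     0.0, 10.0,  10.0, 15.0,   5.0, 10.5,   6.0, 12.0,   8.0,  8.0,
    10.0, 20.0,  12.0,  4.0,  12.0,  6.0,  15.0,  5.0,  10.0, 10.0),
    ncol = 2, byrow = TRUE)
  colnames(m) <- c("CI", "OR")
  m
}

#' Published test-set prediction table
#'
#' Real and predicted concentrations with per-mixture recoveries, as
#' reported for the elected Bayesian-regularization net (1 hidden layer,
#' 2 neurons). Recovery is undefined (NA) where the true concentration is
#' zero.
#' @return data.frame: real_ci, real_or, pred_ci, pred_or, rec_ci, rec_or
#' @export
referenceTestPredictions <- function() {
  data.frame(
    real_ci = c(0, 10, 5, 6, 8, 10, 12, 12, 15, 10),
    real_or = c(10, 15, 10.5, 12, 8, 20, 4, 6, 5, 10),
    pred_ci = c(0.01, 9.99, 4.93, 5.91, 8.19, 10.18, 12.29, 11.89, 14.87, 9.87),
    pred_or = c(9.89, 15.28, 10.64, 11.73, 7.90, 19.86, 3.92, 6.07, 5.13, 9.88),
    rec_ci = c(NA, 99.87, 98.58, 98.47, 102.42, 101.81, 102.41, 99.09,
               99.11, 98.73),
    rec_or = c(98.93, 101.84, 101.30, 97.76, 98.70, 99.29, 98.02, 101.25,
               102.54, 98.79))
}

#' Synthetic serum blank spectrum
#'
#' A smooth, low-amplitude baseline emulating a protein-depleted serum
#' matrix measured against solvent: a broad short-wave absorption tail plus
#' a gentle seeded degree-2 drift. Subtracting the same blank from a
#' spiked-serum synthetic mixture recovers the plain mixture to within the
#' photometric noise.
#'
#' @param noise a \code{\link{noiseModel}}; its \code{baseline_amp} (or
#'   \code{amplitude}) sets the scale and its seed fixes the drift
#' @param grid a \linkS4class{WavelengthGrid}
#' @param amplitude peak amplitude (AU) of the short-wave tail
#' @return a \linkS4class{Spectrum}
#' @export
serumBlank <- function(noise = noiseModel(), grid = scanGrid(),
                       amplitude = 0.05) {
  lambda <- wavelengths(grid)
  tail_band <- amplitude * exp(-((lambda - 215) / 45)^2)
  drift <- withSeed(noise$seed + 7L, {
    t <- seq(-1, 1, length.out = grid@n_points)
    co <- stats::runif(3, -1, 1) * max(noise$baseline_amp, amplitude / 20)
    co[1] + co[2] * t + co[3] * t^2
  })
  spectrum(grid, tail_band + drift, "serum_blank")
}
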