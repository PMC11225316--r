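#' @import methods
NULL

#' Regular wavelength grid
#'
#' A wavelength axis stored as start/step/count so that grid positions are
#' exactly reproducible (never as a float vector, which accumulates error).
#' Grids are closed intervals: both endpoints are grid points.
#'
#' @slot start_nm first wavelength (nm)
#' @slot step_nm wavelength increment (nm), strictly positive
#' @slot n_points number of grid points (>= 2)
#' @export
setClass("WavelengthGrid",
  representation(start_nm = "numeric", step_nm = "numeric",
                 n_points = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@start_nm) != 1L || !is.finite(object@start_nm))
      msg <- c(msg, "start_nm must be a single finite number")
    if (length(object@step_nm) != 1L || !is.finite(object@step_nm) ||
        object@step_nm <= 0)
      msg <- c(msg, "step_nm must be a single positive number")
    if (length(object@n_points) != 1L || is.na(object@n_points) ||
        object@n_points < 2L)
      msg <- c(msg, "n_points must be >= 2")
    if (is.null(msg)) TRUE else msg
  })

#' Single absorption spectrum on a regular wavelength grid
#'
#' Absorbance values (AU) on a \linkS4class{WavelengthGrid}. Values must be
#' finite except that \code{NA} marks points masked out by ratio-spectrum
#' division (divisor below the floor); masked points are excluded from all
#' downstream wavelength elections and means.
#'
#' @slot grid the wavelength grid
#' @slot absorbance numeric vector, one value per grid point
#' @slot label free-text identifier
#' @export
setClass("Spectrum",
  representation(grid = "WavelengthGrid", absorbance = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@absorbance) != object@grid@n_points)
      msg <- c(msg, "length(absorbance) must equal grid n_points")
    bad <- !is.na(object@absorbance) & !is.finite(object@absorbance)
    if (any(bad))
      msg <- c(msg, "absorbance values must be finite (NA allowed as mask)")
    if (length(object@label) != 1L)
      msg <- c(msg, "label must be a single string")
    if (is.null(msg)) TRUE else msg
  })

#' Collection of spectra sharing one grid, with optional concentrations
#'
#' Absorbances are held as a points x samples matrix (the natural layout for
#' multivariate calibration); the optional concentration matrix is
#' samples x components in ug/ml.
#'
#' @slot grid shared wavelength grid
#' @slot absorbance points x samples numeric matrix
#' @slot concentrations samples x components matrix (ug/ml) or NULL
#' @export
setClass("SpectrumSet",
  representation(grid = "WavelengthGrid", absorbance = "matrix",
                 concentrations = "ANY"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@absorbance) != object@grid@n_points)
      msg <- c(msg, "absorbance rows must equal grid n_points")
    bad <- !is.na(object@absorbance) & !is.finite(object@absorbance)
    if (any(bad))
      msg <- c(msg, "absorbance values must be finite (NA allowed as mask)")
    cc <- object@concentrations
    if (!is.null(cc)) {
      if (!is.matrix(cc) || !is.numeric(cc))
        msg <- c(msg, "concentrations must be a numeric matrix or NULL")
      else {
        if (nrow(cc) != ncol(object@absorbance))
          msg <- c(msg, "concentration rows must equal number of spectra")
        if (any(cc < 0, na.rm = TRUE))
          msg <- c(msg, "concentrations must be >= 0")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' Fourier self-deconvolution parameters
#'
#' \code{fwhm_nm} is the assumed Lorentzian width of the broadening to be
#' removed; the interferogram is multiplied by exp(pi * width * |x|) where,
#' under the default \code{"fwhm"} convention, width is \code{fwhm_nm}
#' itself (exactly cancelling the exp(-pi * FWHM * |x|) Fourier decay of a
#' Lorentzian of that FWHM); under \code{"hwhm"} the supplied value is read
#' as a half-width and doubled.
#'
#' @slot fwhm_nm assumed Lorentzian FWHM (nm)
#' @slot apodization one of "triangular_sq", "boxcar", "triangular",
#'   "bessel_like"
#' @slot apod_fraction fraction (0, 1] of the interferogram retained
#' @slot pad_factor integer >= 1; edge padding multiple suppressing
#'   wrap-around
#' @slot width_convention "fwhm" or "hwhm"
#' @export
setClass("FsdParams",
  representation(fwhm_nm = "numeric", apodization = "character",
                 apod_fraction = "numeric", pad_factor = "integer",
                 width_convention = "character"),
  validity = function(object) {
    msg <- NULL
    if (!(length(object@fwhm_nm) == 1L && is.finite(object@fwhm_nm) &&
          object@fwhm_nm > 0))
      msg <- c(msg, "fwhm_nm must be a single positive number")
    if (!object@apodization %in%
        c("triangular_sq", "boxcar", "triangular", "bessel_like"))
      msg <- c(msg, "unknown apodization")
    if (!(object@apod_fraction > 0 && object@apod_fraction <= 1))
      msg <- c(msg, "apod_fraction must be in (0, 1]")
    if (object@pad_factor < 1L)
      msg <- c(msg, "pad_factor must be >= 1")
    if (!object@width_convention %in% c("fwhm", "hwhm"))
      msg <- c(msg, "width_convention must be 'fwhm' or 'hwhm'")
    if (is.null(msg)) TRUE else msg
  })

#' Ordinary least-squares line fit
#'
#' @slot slope slope (signal units per ug/ml)
#' @slot intercept intercept (signal units)
#' @slot r_squared coefficient of determination
#' @slot residual_sd residual standard deviation (n - 2 denominator)
#' @slot n number of points fitted
#' @export
setClass("LinearFit",
  representation(slope = "numeric", intercept = "numeric",
                 r_squared = "numeric", residual_sd = "numeric",
                 n = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@n < 2L) msg <- c(msg, "n must be >= 2")
    if (!is.na(object@r_squared) &&
        (object@r_squared < -1e-12 || object@r_squared > 1 + 1e-12))
      msg <- c(msg, "r_squared must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' Zero-crossing calibration for Fourier self-deconvolution
#'
#' Linear calibration of the deconvolved signal at a wavelength where the
#' interfering component's deconvolved spectrum crosses zero for every
#' concentration, so the analyte is read without interference.
#'
#' @slot wavelength_nm elected measurement wavelength
#' @slot fit the straight-line calibration
#' @slot fsd_params deconvolution parameters the calibration was built under
#' @slot grid grid the calibration spectra were measured on
#' @export
setClass("ZeroCrossingCalibration",
  representation(wavelength_nm = "numeric", fit = "LinearFit",
                 fsd_params = "FsdParams", grid = "WavelengthGrid"),
  validity = function(object) {
    if (object@fit@slope == 0) "slope must be non-zero" else TRUE
  })

#' Ratio-spectra mean-centering calibration
#'
#' @slot divisor divisor spectrum (pure interferent)
#' @slot divisor_conc divisor concentration (ug/ml)
#' @slot range_nm length-2 numeric, mean-centering wavelength window
#' @slot lambda_max_nm elected measurement wavelength (maximum-response point)
#' @slot fit the straight-line calibration
#' @slot floor division floor (AU)
#' @export
setClass("McCalibration",
  representation(divisor = "Spectrum", divisor_conc = "numeric",
                 range_nm = "numeric", lambda_max_nm = "numeric",
                 fit = "LinearFit", floor = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@range_nm) != 2L || object@range_nm[1] >= object@range_nm[2])
      msg <- c(msg, "range_nm must be (lo, hi) with lo < hi")
    if (object@lambda_max_nm < object@range_nm[1] ||
        object@lambda_max_nm > object@range_nm[2])
      msg <- c(msg, "lambda_max_nm must lie inside range_nm")
    if (object@fit@slope == 0)
      msg <- c(msg, "slope must be non-zero")
    if (is.null(msg)) TRUE else msg
  })

#' Trained feed-forward calibration network
#'
#' Weights and biases of a TANSIG-hidden / PURELIN-output net together with
#' the min-max scaling that maps inputs and targets to [-1, 1], the training
#' history, and (for Bayesian regularization) the effective number of
#' parameters gamma.
#'
#' @slot config list: n_inputs, hidden (vector of neuron counts), n_outputs
#' @slot weights list of layers, each list(W = matrix, b = vector)
#' @slot scaling list: in_min, in_max, out_min, out_max
#' @slot history data.frame of per-epoch diagnostics
#' @slot algorithm "lm" or "br"
#' @slot epochs_run integer
#' @slot gamma effective number of parameters (NA for LM)
#' @slot seed RNG seed the run was initialized with
#' @export
setClass("TrainedNet",
  representation(config = "list", weights = "list", scaling = "list",
                 history = "data.frame", algorithm = "character",
                 epochs_run = "integer", gamma = "numeric",
                 seed = "integer"))

#' RGB-12 whiteness scorecard
#'
#' @slot red safety / toxicity / energy criterion scores (0-100)
#' @slot green trueness / precision / limits criterion scores (0-100)
#' @slot blue cost / speed / simplicity criterion scores (0-100)
#' @slot group_means named vector of the three group means
#' @slot whiteness overall score, mean of the three group means
#' @export
setClass("WhitenessScore",
  representation(red = "numeric", green = "numeric", blue = "numeric",
                 group_means = "numeric", whiteness = "numeric"),
  validity = function(object) {
    all_scores <- c(object@red, object@green, object@blue)
    if (any(all_scores < 0 | all_scores > 100))
      "all criterion scores must lie in [0, 100]"
    else TRUE
  })
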