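#' Construct a regular wavelength grid
#'
#' @param start_nm first wavelength (nm)
#' @param step_nm increment (nm), > 0
#' @param n_points number of points (>= 2); alternatively give \code{end_nm}
#' @param end_nm last wavelength (nm); used only when \code{n_points} is
#'   missing, and must be \code{start_nm + k * step_nm} for integer k
#' @return a \linkS4class{WavelengthGrid}
#' @examples
#' wavelengthGrid(200, 0.1, end_nm = 400)
#' @export
wavelengthGrid <- function(start_nm, step_nm, n_points = NULL, end_nm = NULL) {
  if (is.null(n_points)) {
    if (is.null(end_nm))
      stop("give either n_points or end_nm")
    k <- (end_nm - start_nm) / step_nm
    if (abs(k - round(k)) > 1e-6)
      stop("end_nm is not an integer number of steps from start_nm")
    n_points <- as.integer(round(k)) + 1L
  }
  new("WavelengthGrid", start_nm = as.numeric(start_nm),
      step_nm = as.numeric(step_nm), n_points = as.integer(n_points))
}

#' Last wavelength of a grid
#' @param g a \linkS4class{WavelengthGrid}
#' @return wavelength (nm)
#' @export
gridEnd <- function(g) g@start_nm + (g@n_points - 1L) * g@step_nm

#' @describeIn wavelengths positions of a grid
#' @export
setMethod("wavelengths", "WavelengthGrid", function(x)
  x@start_nm + (seq_len(x@n_points) - 1L) * x@step_nm)

#' Wavelength positions
#'
#' @param x a grid, spectrum or spectrum set
#' @return numeric vector of wavelengths (nm)
#' @name wavelengths
NULL

#' @describeIn wavelengths positions of a spectrum's grid
#' @export
setMethod("wavelengths", "Spectrum", function(x) wavelengths(x@grid))

#' @describeIn wavelengths positions of a set's shared grid
#' @export
setMethod("wavelengths", "SpectrumSet", function(x) wavelengths(x@grid))

#' Number of grid points
#' @param x a grid, spectrum or spectrum set
#' @name nPoints
NULL

#' @describeIn nPoints of a grid
#' @export
setMethod("nPoints", "WavelengthGrid", function(x) x@n_points)
#' @describeIn nPoints of a spectrum
#' @export
setMethod("nPoints", "Spectrum", function(x) x@grid@n_points)
#' @describeIn nPoints of a set
#' @export
setMethod("nPoints", "SpectrumSet", function(x) x@grid@n_points)

#' Absorbance values
#' @param x a spectrum (vector) or spectrum set (points x samples matrix)
#' @name absorbance
NULL

#' @describeIn absorbance of a spectrum
#' @export
setMethod("absorbance", "Spectrum", function(x) x@absorbance)
#' @describeIn absorbance of a set
#' @export
setMethod("absorbance", "SpectrumSet", function(x) x@absorbance)

#' Concentration matrix of a spectrum set
#' @param x a \linkS4class{SpectrumSet}
#' @return samples x components matrix (ug/ml) or NULL
#' @name concentrations
NULL

#' @describeIn concentrations accessor
#' @export
setMethod("concentrations", "SpectrumSet", function(x) x@concentrations)

#' Construct a spectrum
#'
#' @param grid a \linkS4class{WavelengthGrid}
#' @param absorbance numeric vector, one value per grid point
#' @param label identifier
#' @return a \linkS4class{Spectrum}
#' @export
spectrum <- function(grid, absorbance, label = "") {
  new("Spectrum", grid = grid, absorbance = as.numeric(absorbance),
      label = as.character(label)[1])
}

#' Construct a spectrum set
#'
#' @param spectra list of \linkS4class{Spectrum} sharing one grid, or a
#'   points x samples matrix together with \code{grid}
#' @param concentrations optional samples x components matrix (ug/ml)
#' @param grid required when \code{spectra} is a matrix
#' @return a \linkS4class{SpectrumSet}
#' @export
spectrumSet <- function(spectra, concentrations = NULL, grid = NULL) {
  if (is.list(spectra)) {
    if (!length(spectra)) stop("empty spectrum list")
    grid <- spectra[[1]]@grid
    for (s in spectra)
      if (!sameGrid(s@grid, grid))
        stop("all member spectra must share an identical grid")
    mat <- vapply(spectra, function(s) s@absorbance,
                  numeric(grid@n_points))
    mat <- matrix(mat, nrow = grid@n_points)
    colnames(mat) <- vapply(spectra, function(s) s@label, character(1))
  } else {
    if (is.null(grid)) stop("grid required when spectra is a matrix")
    mat <- as.matrix(spectra)
  }
  if (!is.null(concentrations)) concentrations <- as.matrix(concentrations)
  new("SpectrumSet", grid = grid, absorbance = mat,
      concentrations = concentrations)
}

#' Extract one spectrum from a set
#' @param x a \linkS4class{SpectrumSet}
#' @param i sample index
#' @return a \linkS4class{Spectrum}
#' @export
getSpectrum <- function(x, i) {
  lab <- colnames(x@absorbance)[i]
  spectrum(x@grid, x@absorbance[, i], if (is.null(lab) || is.na(lab)) "" else lab)
}

#' Number of spectra in a set
#' @param x a \linkS4class{SpectrumSet}
#' @export
nSpectra <- function(x) ncol(x@absorbance)

sameGrid <- function(a, b, tol = 1e-9) {
  a@n_points == b@n_points &&
    abs(a@start_nm - b@start_nm) < tol &&
    abs(a@step_nm - b@step_nm) < tol
}

#' Index of the grid point nearest a wavelength
#'
#' @param g a \linkS4class{WavelengthGrid}
#' @param nm wavelength (nm); vectorized
#' @param exact require the wavelength to sit on the grid (within 1e-6 nm)
#' @return integer index (1-based)
#' @export
gridIndex <- function(g, nm, exact = FALSE) {
  k <- (nm - g@start_nm) / g@step_nm
  if (exact && any(abs(k - round(k)) > 1e-6))
    stop("wavelength not on grid: ", paste(nm[abs(k - round(k)) > 1e-6],
                                           collapse = ", "))
  i <- as.integer(round(k)) + 1L
  if (any(i < 1L | i > g@n_points))
    stop("wavelength outside grid range")
  i
}

setMethod("show", "WavelengthGrid", function(object) {
  cat(sprintf("WavelengthGrid: %.4g-%.4g nm, step %.4g nm, %d points\n",
              object@start_nm, gridEnd(object), object@step_nm,
              object@n_points))
})

setMethod("show", "Spectrum", function(object) {
  nm <- sum(is.na(object@absorbance))
  cat(sprintf("Spectrum%s: %.4g-%.4g nm (step %.4g), %d points%s\n",
              if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
              object@grid@start_nm, gridEnd(object@grid),
              object@grid@step_nm, object@grid@n_points,
              if (nm) sprintf(", %d masked", nm) else ""))
})

setMethod("show", "SpectrumSet", function(object) {
  cat(sprintf("SpectrumSet: %d spectra, %.4g-%.4g nm (step %.4g)%s\n",
              ncol(object@absorbance), object@grid@start_nm,
              gridEnd(object@grid), object@grid@step_nm,
              if (is.null(object@concentrations)) ""
              else sprintf(", %d-component concentrations",
                           ncol(object@concentrations))))
})

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; target positions coinciding with source grid
#' points (within 1e-9 nm) take the source value unchanged, so resampling a
#' 0.1 nm scan to a 0.5 nm grid is plain decimation.
#'
#' @param x a \linkS4class{Spectrum}
#' @param target a \linkS4class{WavelengthGrid} whose range lies within the
#'   source range
#' @return a \linkS4class{Spectrum} on \code{target}
#' @name resample
NULL

#' @describeIn resample linear-interpolation resampling
#' @export
setMethod("resample", signature("Spectrum", "WavelengthGrid"),
  function(x, target) {
    src <- x@grid
    if (target@start_nm < src@start_nm - 1e-9 ||
        gridEnd(target) > gridEnd(src) + 1e-9)
      stop("target grid extends outside the source range")
    pos <- wavelengths(target)
    k <- (pos - src@start_nm) / src@step_nm
    k0 <- floor(k + 1e-9)
    frac <- k - k0
    on_grid <- abs(frac) < 1e-9 / src@step_nm
    i0 <- pmin(pmax(as.integer(k0) + 1L, 1L), src@n_points)
    i1 <- pmin(i0 + 1L, src@n_points)
    y <- (1 - frac) * x@absorbance[i0] + frac * x@absorbance[i1]
    y[on_grid] <- x@absorbance[i0[on_grid]]
    spectrum(target, y, x@label)
  })

#' Slice a spectrum or set to a wavelength window
#'
#' \code{lo_nm} and \code{hi_nm} snap to the nearest grid points; the result
#' keeps the original step. Slicing 279.0-316.0 nm of a 0.5 nm grid yields
#' exactly 75 points.
#'
#' @param x a \linkS4class{Spectrum} or \linkS4class{SpectrumSet}
#' @param lo_nm,hi_nm window bounds (nm), inside the grid range
#' @return object of the same class on the sliced grid
#' @name sliceRange
NULL

sliceIndices <- function(g, lo_nm, hi_nm) {
  if (lo_nm > hi_nm) stop("empty slice: lo_nm > hi_nm")
  i0 <- gridIndex(g, lo_nm)
  i1 <- gridIndex(g, hi_nm)
  if (i1 < i0) stop("empty slice")
  i0:i1
}

#' @describeIn sliceRange slice a spectrum
#' @export
setMethod("sliceRange", "Spectrum", function(x, lo_nm, hi_nm) {
  idx <- sliceIndices(x@grid, lo_nm, hi_nm)
  g <- wavelengthGrid(x@grid@start_nm + (idx[1] - 1L) * x@grid@step_nm,
                      x@grid@step_nm, length(idx))
  spectrum(g, x@absorbance[idx], x@label)
})

#' @describeIn sliceRange slice every spectrum of a set
#' @export
setMethod("sliceRange", "SpectrumSet", function(x, lo_nm, hi_nm) {
  idx <- sliceIndices(x@grid, lo_nm, hi_nm)
  g <- wavelengthGrid(x@grid@start_nm + (idx[1] - 1L) * x@grid@step_nm,
                      x@grid@step_nm, length(idx))
  new("SpectrumSet", grid = g,
      absorbance = x@absorbance[idx, , drop = FALSE],
      concentrations = x@concentrations)
})

#' Pointwise ratio of two spectra with floor masking
#'
#' Ratio-spectra methods blow up where the divisor vanishes; grid points
#' where |divisor| < \code{floor} are therefore masked (\code{NA}) rather
#' than producing huge ratios, and downstream operations skip them.
#'
#' @param numerator,divisor spectra on an identical grid
#' @param floor positive divisor magnitude (AU) below which points are masked
#' @return a \linkS4class{Spectrum}; masked points are \code{NA}
#' @export
divideSpectrum <- function(numerator, divisor, floor = 1e-3) {
  if (!sameGrid(numerator@grid, divisor@grid))
    stop("grid mismatch between numerator and divisor")
  if (!(floor > 0)) stop("floor must be > 0")
  d <- divisor@absorbance
  y <- numerator@absorbance / d
  y[is.na(d) | abs(d) < floor] <- NA_real_
  spectrum(numerator@grid, y, numerator@label)
}
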