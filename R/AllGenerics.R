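#' @rdname wavelengths
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @rdname absorbance
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))

#' @rdname nPoints
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname concentrations
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname resample
#' @export
setGeneric("resample", function(x, target) standardGeneric("resample"))

#' @rdname sliceRange
#' @export
setGeneric("sliceRange", function(x, lo_nm, hi_nm) standardGeneric("sliceRange"))
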