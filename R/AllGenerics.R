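#' @import methods
#' @importFrom BiocGenerics counts
#' @importFrom stats approx coef lm mad median nls quantile resid rexp rlnorm
#'   rnorm rpois runif sd setNames var plnorm qlnorm predict
#' @importFrom utils head read.csv tail write.csv packageVersion
NULL

#' Pixel size of an image-like object
#'
#' @param object a [Kymograph-class] or similar object.
#' @return Pixel size in nanometres.
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' Scan-line period of a kymograph
#'
#' @param object a [Kymograph-class].
#' @return Line period in seconds.
#' @export
setGeneric("linePeriod", function(object) standardGeneric("linePeriod"))

#' Calibrated photon yields
#'
#' Accessors for the single-fluorophore and per-tetramer photon yields of a
#' [Calibration-class] object. The tetramer value is exactly four times the
#' single-fluorophore value (four labels per tetramer).
#'
#' @param object a [Calibration-class].
#' @return Photons per confocal scan line.
#' @export
setGeneric("photonsPerFluor", function(object) standardGeneric("photonsPerFluor"))

#' @rdname photonsPerFluor
#' @export
setGeneric("photonsPerTetramer",
           function(object) standardGeneric("photonsPerTetramer"))

#' Classification of a trajectory
#'
#' @param object a [Trajectory-class].
#' @return `"diffusive"`, `"static"` or `"ambiguous"`.
#' @export
setGeneric("classification", function(object) standardGeneric("classification"))
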