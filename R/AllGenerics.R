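#' @import methods
NULL

#' Pixel matrix of an image-like object
#'
#' @param object a \linkS4class{TiledWellImage}.
#' @return Numeric matrix of intensities in \[0, 1\], indexed \[row, col\].
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname pixels
#' @param value replacement pixel matrix (values in \[0, 1\]).
#' @export
setGeneric("pixels<-", function(object, value) standardGeneric("pixels<-"))

#' Well identifier of an object
#' @param object an object carrying well identity.
#' @return Character scalar such as \code{"A1"}.
#' @export
setGeneric("wellId", function(object) standardGeneric("wellId"))

#' Plate identifier of an object
#' @param object an object carrying plate identity.
#' @return Character scalar.
#' @export
setGeneric("plateId", function(object) standardGeneric("plateId"))

#' Timepoint (days) of an object
#' @param object an object carrying a timepoint.
#' @return Numeric scalar, days since the start of the experiment.
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' Fitted well center
#' @param object a \linkS4class{WellMask} or \linkS4class{GroundTruth}.
#' @return Numeric (row, col) in pixels.
#' @export
setGeneric("wellCenter", function(object) standardGeneric("wellCenter"))

#' Fitted well radius
#' @param object a \linkS4class{WellMask} or \linkS4class{GroundTruth}.
#' @return Numeric scalar, pixels.
#' @export
setGeneric("wellRadius", function(object) standardGeneric("wellRadius"))

#' Eccentricity of the detected well region
#' @param object a \linkS4class{WellMask}.
#' @return Numeric in \[0, 1): 0 for a circle.
#' @export
setGeneric("eccentricity", function(object) standardGeneric("eccentricity"))

#' Gain surface of an illumination field
#' @param object an \linkS4class{IlluminationField}.
#' @return Numeric matrix of gains in (0, 1\].
#' @export
setGeneric("gain", function(object) standardGeneric("gain"))
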