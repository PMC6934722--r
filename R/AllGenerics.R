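#' @rdname SlideImage-class
#' @param object,x a \linkS4class{SlideImage} or
#'   \linkS4class{SegmentationBundle}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname SlideImage-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname SlideImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname SlideImage-class
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname SlideImage-class
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))

#' @rdname SlideImage-class
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname SegmentationBundle-class
#' @param x a \linkS4class{SegmentationBundle}.
#' @param which mask name: \code{"tissue"}, \code{"nuclei"}, \code{"marker"}
#'   or \code{"markerInNuclei"}.
#' @export
setGeneric("getMask", function(x, which) standardGeneric("getMask"))

#' @rdname SegmentationBundle-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ThresholdResult-class
#' @param x a \linkS4class{ThresholdResult}.
#' @export
setGeneric("thresholdValue", function(x) standardGeneric("thresholdValue"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("criterionValue", function(x) standardGeneric("criterionValue"))

#' @rdname ThresholdResult-class
#' @export
setGeneric("criterionCurve", function(x) standardGeneric("criterionCurve"))
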