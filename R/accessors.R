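#' @rdname SlideImage-class
#' @export
setMethod("channelNames", "SlideImage", function(x) names(x@channels))

#' @rdname SlideImage-class
#' @export
setMethod("getChannel", "SlideImage", function(x, name) {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'; available: ",
         paste(names(x@channels), collapse = ", "))
  x@channels[[name]]
})

#' @rdname SlideImage-class
#' @export
setMethod("pixelSize", "SlideImage", function(x) x@pixelSize)

#' @rdname SlideImage-class
#' @export
setMethod("imageId", "SlideImage", function(x) x@imageId)

#' @rdname SlideImage-class
#' @export
setMethod("artifactMask", "SlideImage", function(x) x@artifactMask)

#' @rdname SlideImage-class
#' @export
setMethod("bitDepth", "SlideImage", function(x) x@bitDepth)

setMethod("dim", "SlideImage", function(x) dim(x@channels[[1L]]))

setMethod("show", "SlideImage", function(object) {
  d <- dim(object)
  cat(sprintf("SlideImage '%s': %d x %d px (%d-bit), %.3f um/px\n",
              object@imageId, d[1L], d[2L], object@bitDepth, object@pixelSize))
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  if (is.null(object@artifactMask)) {
    cat("  artifact mask: none\n")
  } else {
    cat(sprintf("  artifact mask: %d px excluded\n", sum(object@artifactMask)))
  }
  invisible(NULL)
})

#' @rdname SegmentationBundle-class
#' @export
setMethod("getMask", "SegmentationBundle", function(x, which) {
  which <- match.arg(which, c("tissue", "nuclei", "marker", "markerInNuclei"))
  slot(x, which)
})

#' @rdname SegmentationBundle-class
#' @export
setMethod("thresholds", "SegmentationBundle", function(x) x@thresholds)

#' @rdname SegmentationBundle-class
#' @export
setMethod("imageId", "SegmentationBundle", function(x) x@imageId)

setMethod("show", "SegmentationBundle", function(object) {
  d <- dim(object@tissue)
  cat(sprintf("SegmentationBundle '%s': %d x %d px\n",
              object@imageId, d[1L], d[2L]))
  for (s in c("tissue", "nuclei", "marker", "markerInNuclei")) {
    th <- object@thresholds[[sub("markerInNuclei", "marker", s)]]
    cat(sprintf("  %-15s %8d px%s\n", s, sum(slot(object, s)),
                if (s != "markerInNuclei" && !is.null(th))
                  sprintf("  (%s threshold %d)", th@method, th@threshold)
                else ""))
  }
  if (object@excludedAreaPx > 0L)
    cat(sprintf("  excluded:       %8d px\n", object@excludedAreaPx))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  invisible(NULL)
})

#' @rdname ThresholdResult-class
#' @export
setMethod("thresholdValue", "ThresholdResult", function(x) x@threshold)

#' @rdname ThresholdResult-class
#' @export
setMethod("criterionValue", "ThresholdResult", function(x) x@criterionValue)

#' @rdname ThresholdResult-class
#' @export
setMethod("criterionCurve", "ThresholdResult", function(x) x@criterionCurve)

setMethod("show", "ThresholdResult", function(object) {
  cat(sprintf("ThresholdResult: %s threshold = %d (criterion %.6g)\n",
              object@method, object@threshold, object@criterionValue))
  invisible(NULL)
})
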