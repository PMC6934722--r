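# Gaussian kernel of total width `width` pixels: sigma = width/3, support
# truncated at +/- width/2. "Width" is the full kernel footprint, so a
# 5-pixel-wide filter is a 5x5 kernel with sigma 5/3.
.gaussianKernel <- function(width = 5) {
  half <- floor(width / 2)
  sigma <- width / 3
  g <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

.emptyMask <- function(d) matrix(FALSE, d[1L], d[2L])

# Threshold one raster with artifact exclusion; degenerate histograms yield
# an empty mask plus a warning string instead of an error, so batch runs
# survive blank sections.
.thresholdChannel <- function(raster, exclude, bitDepth, method, label) {
  counts <- intensityHistogram(raster, exclude = exclude, bitDepth = bitDepth)
  res <- tryCatch(
    if (method == "otsu") otsuThreshold(counts) else kapurThreshold(counts),
    degenerateHistogram = function(e) e
  )
  if (inherits(res, "degenerateHistogram")) {
    warn <- sprintf("%s: %s; empty mask returned", label, conditionMessage(res))
    warning(warn, call. = FALSE)
    return(list(mask = .emptyMask(dim(raster)), threshold = NULL,
                warning = warn))
  }
  mask <- binarize(raster, res, bitDepth = bitDepth)
  if (!is.null(exclude)) mask[exclude] <- FALSE
  list(mask = mask, threshold = res, warning = character(0))
}

#' Total tissue mask
#'
#' Tissue is almost entirely represented by the DAPI and autofluorescence
#' signals. Those channels are combined pixelwise (maximum by default, sum
#' optionally; nuclei alone when no autofluorescence channel is present),
#' smoothed with a Gaussian filter of total width \code{smoothWidth} pixels,
#' and binarised with Otsu's method. Artifact-excluded pixels are omitted
#' from the histogram and forced out of the mask.
#'
#' @param image a \linkS4class{SlideImage} with a \code{nuclei} channel.
#' @param smoothWidth Gaussian kernel width in pixels (default 5; sigma =
#'   width/3, support truncated at width/2).
#' @param combine how DAPI and autofluorescence are merged: \code{"max"}
#'   (default) or \code{"sum"}.
#' @return \code{list(mask, threshold, warning)} — the binary tissue mask,
#'   the \linkS4class{ThresholdResult} (or \code{NULL} for a blank image),
#'   and any degenerate-channel warning.
#' @export
tissueMask <- function(image, smoothWidth = 5, combine = c("max", "sum")) {
  stopifnot(is(image, "SlideImage"))
  combine <- match.arg(combine)
  image <- applyArtifactMask(image)
  src <- getChannel(image, "nuclei")
  if ("autofluorescence" %in% channelNames(image)) {
    af <- getChannel(image, "autofluorescence")
    src <- if (combine == "max") pmax(src, af)
           else pmin(src + af, 2^image@bitDepth - 1)
    dim(src) <- dim(image)
  }
  sm <- EBImage::filter2(src, .gaussianKernel(smoothWidth),
                         boundary = "replicate")
  sm <- round(pmin(pmax(sm, 0), 2^image@bitDepth - 1))
  storage.mode(sm) <- "integer"
  .thresholdChannel(sm, image@artifactMask, image@bitDepth, "otsu",
                    paste0(image@imageId, " tissue channel"))
}

#' Nuclei (DAPI) mask
#'
#' Otsu binarisation of the unsmoothed nuclei channel, artifact-excluded.
#'
#' @inheritParams tissueMask
#' @return as [tissueMask()].
#' @export
nucleiMask <- function(image) {
  stopifnot(is(image, "SlideImage"))
  image <- applyArtifactMask(image)
  .thresholdChannel(getChannel(image, "nuclei"), image@artifactMask,
                    image@bitDepth, "otsu",
                    paste0(image@imageId, " nuclei channel"))
}

#' Marker (Ki67 or TUNEL) mask
#'
#' Kapur maximum-entropy binarisation of the marker channel, artifact
#' excluded. The contract is identical for proliferation and apoptosis
#' markers.
#'
#' @inheritParams tissueMask
#' @return as [tissueMask()].
#' @export
markerMask <- function(image) {
  stopifnot(is(image, "SlideImage"))
  image <- applyArtifactMask(image)
  .thresholdChannel(getChannel(image, "marker"), image@artifactMask,
                    image@bitDepth, "kapur",
                    paste0(image@imageId, " marker channel"))
}

#' Restrict a marker mask to nuclei
#'
#' Specific marker staining can only occur within nuclei, so the binarised
#' marker and nuclei masks are multiplied (pixelwise AND) to omit unspecific
#' staining outside of nuclei.
#'
#' @param marker,nuclei logical matrices of equal dimensions.
#' @return logical matrix, a subset of both inputs.
#' @export
restrictToNuclei <- function(marker, nuclei) {
  if (!identical(dim(marker), dim(nuclei)))
    stop(sprintf("mask dimensions differ: marker %dx%d vs nuclei %dx%d",
                 nrow(marker), ncol(marker), nrow(nuclei), ncol(nuclei)))
  marker & nuclei
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of component labels (background 0, components
#'   numbered from 1) with attribute \code{nComponents}.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  .labelComponents(mask, as.integer(connectivity))
}

#' Remove small segments from a mask
#'
#' Clears every connected component of up to \code{maxSize} pixels, the step
#' that eliminates specks of fluorescent particles within nuclei. Components
#' of \code{maxSize + 1} pixels or more are retained intact. Idempotent.
#'
#' @param mask logical matrix.
#' @param maxSize largest component size removed, inclusive (default 20).
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix.
#' @export
clearSmallSegments <- function(mask, maxSize = 20L, connectivity = 8L) {
  stopifnot(maxSize >= 0)
  if (!any(mask)) return(mask)
  labels <- labelComponents(mask, connectivity)
  n <- attr(labels, "nComponents")
  if (n == 0L) return(mask)
  sizes <- tabulate(labels[labels > 0L], nbins = n)
  keep <- c(FALSE, sizes > maxSize)   # index 1 = background label 0
  out <- keep[labels + 1L]
  dim(out) <- dim(mask)
  out
}

#' Segment one slide image into the four pipeline masks
#'
#' Runs the full single-image segmentation: optional linear unmixing, then
#' tissue mask (merge DAPI + autofluorescence, Gaussian smooth, Otsu), nuclei
#' mask (Otsu on DAPI), marker mask (Kapur on Ki67/TUNEL), restriction of the
#' marker to nuclei by mask multiplication, and clearing of small segments
#' from the nuclear-restricted marker mask (optionally also from the nuclei
#' mask). Degenerate (blank or single-valued) channels produce empty masks
#' with collected warnings rather than errors.
#'
#' @param image a \linkS4class{SlideImage} with \code{nuclei} and
#'   \code{marker} channels.
#' @param mixing optional mixing matrix; when supplied the image is unmixed
#'   before any thresholding.
#' @param smoothWidth Gaussian width for the tissue mask (default 5 px).
#' @param combine tissue-channel merge rule, \code{"max"} or \code{"sum"}.
#' @param maxSpeckSize largest segment cleared from the nuclear-restricted
#'   marker mask, inclusive (default 20 px).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param clearNuclei also clear small segments from the nuclei mask
#'   (default FALSE).
#' @return a \linkS4class{SegmentationBundle}.
#' @export
segmentImage <- function(image, mixing = NULL, smoothWidth = 5,
                         combine = c("max", "sum"), maxSpeckSize = 20L,
                         connectivity = 8L, clearNuclei = FALSE) {
  stopifnot(is(image, "SlideImage"))
  combine <- match.arg(combine)
  if (!"marker" %in% channelNames(image))
    stop("image '", image@imageId, "' has no marker channel")
  if (!is.null(mixing)) image <- unmixImage(image, mixing)
  image <- applyArtifactMask(image)
  tis <- tissueMask(image, smoothWidth = smoothWidth, combine = combine)
  nuc <- nucleiMask(image)
  mar <- markerMask(image)
  nucMask <- nuc$mask
  if (clearNuclei)
    nucMask <- clearSmallSegments(nucMask, maxSpeckSize, connectivity)
  markerNuc <- restrictToNuclei(mar$mask, nucMask)
  markerNuc <- clearSmallSegments(markerNuc, maxSpeckSize, connectivity)
  new("SegmentationBundle",
      tissue = tis$mask, nuclei = nucMask, marker = mar$mask,
      markerInNuclei = markerNuc,
      thresholds = list(tissue = tis$threshold, nuclei = nuc$threshold,
                        marker = mar$threshold),
      imageId = image@imageId,
      excludedAreaPx = as.integer(excludedArea(image)),
      warnings = c(tis$warning, nuc$warning, mar$warning))
}
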