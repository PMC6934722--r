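#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Multichannel slide image
#'
#' Container for one whole-slide fluorescence image: named single-channel
#' intensity rasters (non-negative integers at a common bit depth), the
#' physical pixel size, an optional artifact mask marking pixels excluded
#' from all analysis, and an identifier.
#'
#' Channels are addressed by name only; recognised roles are \code{"nuclei"}
#' (DAPI), \code{"marker"} (Ki67 or TUNEL) and \code{"autofluorescence"}.
#' Rasters are stored row-major with the origin at the top-left.
#'
#' @slot channels named list of integer matrices, all of identical dimensions.
#' @slot pixelSize physical edge length of one pixel in micrometres (> 0).
#' @slot artifactMask \code{NULL}, or a logical matrix of the channel
#'   dimensions; \code{TRUE} pixels are excluded from histograms, masks and
#'   area denominators.
#' @slot imageId opaque image identifier.
#' @slot bitDepth integer, 8 or 16.
#'
#' @seealso [readSlideImage()], [applyArtifactMask()], [segmentImage()]
#' @export
setClass("SlideImage",
  representation(
    channels     = "list",
    pixelSize    = "numeric",
    artifactMask = "matrixOrNULL",
    imageId      = "character",
    bitDepth     = "integer"
  ),
  prototype(pixelSize = 0.325, artifactMask = NULL, imageId = "image",
            bitDepth = 8L)
)

setValidity("SlideImage", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must be a uniquely named list")
  for (nm in names(ch)) {
    x <- ch[[nm]]
    if (!is.matrix(x) || !is.numeric(x))
      return(sprintf("channel '%s' is not a numeric matrix", nm))
    if (any(x < 0)) return(sprintf("channel '%s' has negative intensities", nm))
  }
  d <- dim(ch[[1L]])
  for (nm in names(ch)) {
    if (!identical(dim(ch[[nm]]), d))
      return(sprintf("channel dimensions differ: '%s' is %dx%d but '%s' is %dx%d",
                     names(ch)[1L], d[1L], d[2L], nm,
                     dim(ch[[nm]])[1L], dim(ch[[nm]])[2L]))
  }
  if (!is.null(object@artifactMask)) {
    if (!is.logical(object@artifactMask))
      return("artifactMask must be a logical matrix")
    if (!identical(dim(object@artifactMask), d))
      return(sprintf("artifactMask is %dx%d but channels are %dx%d",
                     dim(object@artifactMask)[1L], dim(object@artifactMask)[2L],
                     d[1L], d[2L]))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (!object@bitDepth %in% c(8L, 16L))
    return("bitDepth must be 8 or 16")
  mx <- 2^object@bitDepth - 1
  for (nm in names(ch))
    if (max(ch[[nm]]) > mx)
      return(sprintf("channel '%s' exceeds the %d-bit range", nm, object@bitDepth))
  TRUE
})

#' Result of a global histogram thresholding
#'
#' @slot threshold integer in [0, 255]; foreground is strictly greater than
#'   the threshold.
#' @slot criterionValue the objective evaluated at the returned threshold.
#' @slot method \code{"otsu"} or \code{"kapur"}.
#' @slot criterionCurve the objective at every candidate threshold 0..255
#'   (\code{NA} where a class is empty), so either optimisation convention can
#'   be audited.
#'
#' @seealso [otsuThreshold()], [kapurThreshold()]
#' @export
setClass("ThresholdResult",
  representation(
    threshold      = "integer",
    criterionValue = "numeric",
    method         = "character",
    criterionCurve = "numeric"
  )
)

setValidity("ThresholdResult", function(object) {
  if (object@threshold < 0L || object@threshold > 255L)
    return("threshold must lie in [0, 255]")
  if (!object@method %in% c("otsu", "kapur"))
    return("method must be 'otsu' or 'kapur'")
  if (length(object@criterionCurve) != 256L)
    return("criterionCurve must have 256 values")
  TRUE
})

#' Segmentation masks of one slide image
#'
#' The four binary masks of the quantification pipeline: total tissue,
#' nuclei (DAPI), marker (Ki67/TUNEL), and the nuclear-restricted marker mask
#' after speck clearing, together with the thresholds used. Masks never
#' intersect the artifact-excluded region, and \code{markerInNuclei} is a
#' pixelwise subset of both \code{nuclei} and \code{marker}.
#'
#' @slot tissue,nuclei,marker,markerInNuclei logical matrices of the image
#'   dimensions.
#' @slot thresholds named list of [ThresholdResult-class] objects (entries
#'   \code{tissue}, \code{nuclei}, \code{marker}; \code{NULL} for degenerate
#'   channels).
#' @slot imageId identifier of the segmented image.
#' @slot excludedAreaPx number of artifact-excluded pixels.
#' @slot warnings character vector of degenerate-channel warnings collected
#'   during segmentation.
#'
#' @seealso [segmentImage()], [quantifyBundle()]
#' @export
setClass("SegmentationBundle",
  representation(
    tissue         = "matrix",
    nuclei         = "matrix",
    marker         = "matrix",
    markerInNuclei = "matrix",
    thresholds     = "list",
    imageId        = "character",
    excludedAreaPx = "integer",
    warnings       = "character"
  )
)

setValidity("SegmentationBundle", function(object) {
  d <- dim(object@tissue)
  for (s in c("tissue", "nuclei", "marker", "markerInNuclei")) {
    m <- slot(object, s)
    if (!is.logical(m)) return(sprintf("%s mask must be logical", s))
    if (!identical(dim(m), d)) return(sprintf("%s mask dimensions differ", s))
  }
  if (any(object@markerInNuclei & !object@nuclei))
    return("markerInNuclei is not a subset of nuclei")
  if (any(object@markerInNuclei & !object@marker))
    return("markerInNuclei is not a subset of marker")
  TRUE
})

#' Synthetic slide scene specification
#'
#' Parameters of one synthetic multichannel slide: image geometry, the
#' clustered nuclear population, the marker-positive subpopulation, intensity
#' levels, noise, inter-channel bleedthrough, blooming halos and sub-nuclear
#' fluorescent specks. Defaults describe a desk-scale 512x512 slide with 200
#' nuclei and additive Gaussian noise with standard deviation equal to 10%
#' of the 8-bit dynamic range.
#'
#' @slot dims image dimensions (rows, columns).
#' @slot nNuclei number of nuclei to place.
#' @slot radiusRange nucleus radius range in pixels.
#' @slot positiveFraction fraction of nuclei carrying marker signal in [0, 1];
#'   exactly \code{floor(positiveFraction * nNuclei)} nuclei are positive.
#' @slot background,autofluorescence,nucleusIntensity,markerIntensity
#'   8-bit intensity levels of the scene components.
#' @slot noiseSD standard deviation of the additive Gaussian read noise.
#' @slot bleedthrough square channel-mixing matrix applied to the pure
#'   channels (identity = no bleedthrough).
#' @slot haloWidth width in pixels of the blooming halo around nuclei.
#' @slot haloFraction halo intensity as a fraction of the parent signal.
#' @slot speckCount number of fluorescent specks added to the marker channel.
#' @slot speckSizeRange speck area range in pixels (kept at or below 20 so
#'   that speck clearing is exercised).
#' @slot pixelSize physical pixel size in micrometres.
#'
#' @seealso [sceneSpec()], [generateSlide()], [generateCohort()]
#' @export
setClass("SceneSpec",
  representation(
    dims             = "integer",
    nNuclei          = "integer",
    radiusRange      = "numeric",
    positiveFraction = "numeric",
    background       = "numeric",
    autofluorescence = "numeric",
    nucleusIntensity = "numeric",
    markerIntensity  = "numeric",
    noiseSD          = "numeric",
    bleedthrough     = "matrix",
    haloWidth        = "numeric",
    haloFraction     = "numeric",
    speckCount       = "integer",
    speckSizeRange   = "numeric",
    pixelSize        = "numeric"
  )
)

setValidity("SceneSpec", function(object) {
  if (length(object@dims) != 2L || any(object@dims < 16L))
    return("dims must be two integers >= 16")
  if (object@nNuclei < 0L) return("nNuclei must be >= 0")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    return("positiveFraction must lie in [0, 1]")
  lv <- c(object@background, object@autofluorescence,
          object@nucleusIntensity, object@markerIntensity)
  if (any(lv < 0 | lv > 255)) return("intensity levels must lie in [0, 255]")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  if (nrow(object@bleedthrough) != ncol(object@bleedthrough))
    return("bleedthrough matrix must be square")
  if (diff(object@radiusRange) < 0 || object@radiusRange[1L] < 1)
    return("radiusRange must be increasing and >= 1")
  if (any(object@speckSizeRange < 1) || object@speckSizeRange[2L] > 20)
    return("speckSizeRange must lie within [1, 20]")
  TRUE
})
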