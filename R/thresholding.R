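# Both thresholders operate on a 256-bin histogram regardless of input depth;
# 16-bit rasters are rescaled into 256 bins by their observed maximum so the
# exhaustive 256-candidate optimum stays exact and cheap.
.scaleTo256 <- function(raster, bitDepth = 8L) {
  if (bitDepth == 8L) return(raster)
  mx <- max(raster)
  if (mx == 0L) return(raster)
  out <- round(as.numeric(raster) * 255 / mx)
  dim(out) <- dim(raster)
  storage.mode(out) <- "integer"
  out
}

#' 256-bin intensity histogram of a raster
#'
#' @param raster integer matrix of intensities.
#' @param exclude optional logical matrix; \code{TRUE} pixels (hand-masked
#'   artifacts) are omitted from the histogram before threshold selection.
#' @param bitDepth 8 or 16; 16-bit intensities are rescaled into 256 bins by
#'   the raster's observed maximum.
#' @return integer vector of 256 counts, named "0".."255".
#' @export
intensityHistogram <- function(raster, exclude = NULL, bitDepth = 8L) {
  x <- .scaleTo256(raster, bitDepth)
  if (!is.null(exclude)) x <- x[!exclude]
  counts <- tabulate(as.integer(x) + 1L, nbins = 256L)
  names(counts) <- 0:255
  counts
}

.degenerateHistogram <- function(msg) {
  structure(class = c("degenerateHistogram", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

.checkHistogram <- function(counts) {
  if (length(counts) != 256L) stop("histogram must have 256 bins")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop(.degenerateHistogram("empty histogram: no pixels to threshold"))
  if (sum(counts > 0) < 2L)
    stop(.degenerateHistogram(
      "degenerate histogram: all pixels share one intensity bin"))
  as.numeric(counts)
}

#' Otsu's threshold (between-class variance maximisation)
#'
#' Finds the intensity threshold t in [0, 255] maximising the between-class
#' variance \eqn{\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2}, where class
#' 0 comprises bins \eqn{\le t} and class 1 bins \eqn{> t}. Foreground is
#' defined as intensity strictly greater than t. Ties on the criterion
#' plateau are broken towards the smallest t.
#'
#' @param counts 256-bin histogram as from [intensityHistogram()].
#' @return a \linkS4class{ThresholdResult} with the full criterion curve.
#'   A histogram with fewer than two occupied bins raises a
#'   \code{degenerateHistogram} error (callers at pipeline level convert this
#'   into an empty mask plus a warning).
#' @references Otsu, N. (1979) A threshold selection method from gray-level
#'   histograms. IEEE Trans. Syst. Man Cybern. 9, 62-66.
#' @export
otsuThreshold <- function(counts) {
  p <- .checkHistogram(counts)
  n <- sum(p)
  p <- p / n
  levels <- 0:255
  w0 <- cumsum(p)                    # P(class 0) for t = 0..255
  m0 <- cumsum(p * levels)           # unnormalised class-0 mean
  mT <- m0[256L]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  crit <- rep(NA_real_, 256L)
  mu0 <- m0[valid] / w0[valid]
  mu1 <- (mT - m0[valid]) / w1[valid]
  crit[valid] <- w0[valid] * w1[valid] * (mu0 - mu1)^2
  t <- which.max(crit) - 1L          # first (= smallest t) maximum
  new("ThresholdResult", threshold = t, criterionValue = crit[t + 1L],
      method = "otsu", criterionCurve = crit)
}

#' Kapur's threshold (maximum-entropy criterion)
#'
#' Finds the threshold t maximising the sum of Shannon entropies of the
#' normalised background (bins \eqn{\le t}) and foreground (bins \eqn{> t})
#' class distributions, with \eqn{0 \log 0 := 0}. This is the canonical
#' entropy-sum maximisation of Kapur, Sahoo & Wong; the full criterion curve
#' is returned so either optimisation convention can be audited. Foreground
#' is intensity strictly greater than t; plateau ties break to the smallest t.
#'
#' @inheritParams otsuThreshold
#' @return a \linkS4class{ThresholdResult}; degenerate histograms raise a
#'   \code{degenerateHistogram} error as for [otsuThreshold()].
#' @references Kapur, J.N., Sahoo, P.K., Wong, A.K.C. (1985) A new method for
#'   gray-level picture thresholding using the entropy of the histogram.
#'   Comput. Vision Graph. Image Process. 29, 273-285.
#' @export
kapurThreshold <- function(counts) {
  p <- .checkHistogram(counts)
  p <- p / sum(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)
  H0cum <- cumsum(-plogp)
  Htot <- H0cum[256L]
  P1 <- 1 - P0
  valid <- P0 > 0 & P1 > 0
  crit <- rep(NA_real_, 256L)
  crit[valid] <- log(P0[valid]) + H0cum[valid] / P0[valid] +
    log(P1[valid]) + (Htot - H0cum[valid]) / P1[valid]
  t <- which.max(crit) - 1L
  new("ThresholdResult", threshold = t, criterionValue = crit[t + 1L],
      method = "kapur", criterionCurve = crit)
}

#' Binarise a raster at a threshold
#'
#' Foreground is strictly greater than the threshold: \code{mask = x > t}.
#' 16-bit rasters are rescaled into 256 bins exactly as in
#' [intensityHistogram()] so the threshold applies on the same scale it was
#' selected on.
#'
#' @param raster integer matrix.
#' @param t threshold in [0, 255], or a \linkS4class{ThresholdResult}.
#' @param bitDepth 8 or 16.
#' @return logical matrix.
#' @export
binarize <- function(raster, t, bitDepth = 8L) {
  if (is(t, "ThresholdResult")) t <- t@threshold
  stopifnot(t >= 0, t <= 255)
  x <- .scaleTo256(raster, bitDepth)
  m <- x > t
  dim(m) <- dim(raster)
  m
}
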