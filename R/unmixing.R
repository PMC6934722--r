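#' Validate a channel-mixing (bleedthrough) matrix
#'
#' Entry (i, j) of the matrix is the fraction of fluorophore j's signal that
#' appears in detection channel i. The matrix must be square, named,
#' non-negative with a strictly positive diagonal, and invertible; its
#' condition number is reported as a message.
#'
#' @param m numeric matrix with identical row and column channel names.
#' @return the validated matrix (dimnames ordered as given).
#' @export
validateMixingMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("mixing matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("mixing matrix must carry channel names on rows and columns")
  if (!setequal(rownames(m), colnames(m)))
    stop("mixing matrix row and column channel names differ")
  m <- m[, rownames(m), drop = FALSE]
  if (any(m < 0)) stop("mixing matrix entries must be non-negative")
  if (any(diag(m) <= 0)) stop("mixing matrix diagonal must be strictly positive")
  kappa <- tryCatch(kappa(m, exact = TRUE), error = function(e) Inf)
  if (!is.finite(kappa) || abs(det(m)) < .Machine$double.eps * 100)
    stop("mixing matrix is singular or numerically non-invertible")
  message(sprintf("mixing matrix: %d channels, condition number %.3g",
                  nrow(m), kappa))
  m
}

#' Read a mixing matrix from CSV or YAML
#'
#' CSV: header row of channel names, first column of channel names. YAML: a
#' mapping \code{channels: [names]} plus \code{matrix:} rows.
#'
#' @param path file path ending in \code{.csv}, \code{.yml} or \code{.yaml}.
#' @return a validated mixing matrix.
#' @export
readMixingMatrix <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(d)
  } else if (ext %in% c("yml", "yaml")) {
    y <- yaml::read_yaml(path)
    m <- do.call(rbind, y$matrix)
    dimnames(m) <- list(y$channels, y$channels)
  } else stop("unsupported mixing matrix format: ", path)
  validateMixingMatrix(m)
}

#' Apply channel bleedthrough to pure signals
#'
#' Forward model used by the synthetic generator: observed = M %*% pure,
#' per pixel, then rounded and clipped to the bit-depth range.
#'
#' @param channels named list of numeric matrices (pure per-fluorophore
#'   signals).
#' @param mixing mixing matrix whose names cover the channel names.
#' @param maxIntensity clip ceiling (255 for 8-bit).
#' @return named list of mixed integer matrices.
#' @export
mixChannels <- function(channels, mixing, maxIntensity = 255L) {
  nms <- names(channels)
  mixing <- mixing[nms, nms, drop = FALSE]
  d <- dim(channels[[1L]])
  flat <- vapply(channels, as.numeric, numeric(prod(d)))  # pixels x channels
  mixed <- flat %*% t(mixing)
  out <- lapply(seq_along(nms), function(i) {
    x <- matrix(pmin(pmax(round(mixed[, i]), 0), maxIntensity), d[1L], d[2L])
    storage.mode(x) <- "integer"
    x
  })
  names(out) <- nms
  out
}

#' Correct spectral bleedthrough by linear unmixing
#'
#' Each pixel's observed channel vector is multiplied by the inverse of the
#' mixing matrix; negative results are clamped to zero and the output is
#' re-quantised to the image's bit depth. The artifact mask is carried
#' through unchanged. With an identity matrix this is the identity map.
#'
#' @param image a \linkS4class{SlideImage}.
#' @param mixing a validated mixing matrix whose channel names include every
#'   channel of \code{image}, in any order.
#' @return the unmixed \linkS4class{SlideImage}.
#' @export
unmixImage <- function(image, mixing) {
  stopifnot(is(image, "SlideImage"))
  nms <- channelNames(image)
  if (!all(nms %in% rownames(mixing)))
    stop("mixing matrix does not cover channels: ",
         paste(setdiff(nms, rownames(mixing)), collapse = ", "))
  m <- mixing[nms, nms, drop = FALSE]
  if (abs(det(m)) < .Machine$double.eps * 100)
    stop("mixing matrix is singular for channels ", paste(nms, collapse = ", "))
  inv <- solve(m)
  d <- dim(image)
  flat <- vapply(image@channels, as.numeric, numeric(prod(d)))
  pure <- flat %*% t(inv)
  mx <- 2^image@bitDepth - 1
  image@channels <- stats::setNames(lapply(seq_along(nms), function(i) {
    x <- matrix(pmin(pmax(round(pure[, i]), 0), mx), d[1L], d[2L])
    storage.mode(x) <- "integer"
    x
  }), nms)
  validObject(image)
  image
}
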