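#' Construct a SlideImage from in-memory rasters
#'
#' @param channels named list of non-negative integer matrices with identical
#'   dimensions; recognised names are \code{nuclei}, \code{marker} and
#'   \code{autofluorescence}.
#' @param pixelSize pixel edge length in micrometres. The slide-scanner export
#'   convention of this pipeline is 0.325 um per pixel.
#' @param artifactMask optional logical matrix (or 0/1 raster) of the channel
#'   dimensions; any nonzero/\code{TRUE} pixel is excluded from all analysis.
#' @param imageId identifier carried into all downstream tables.
#' @param bitDepth 8 or 16; inferred from the channel maxima when missing.
#' @return a validated \linkS4class{SlideImage}.
#' @examples
#' img <- SlideImage(list(nuclei = matrix(0L, 10, 10)), imageId = "blank")
#' dim(img)
#' @export
SlideImage <- function(channels, pixelSize = 0.325, artifactMask = NULL,
                       imageId = "image", bitDepth = NULL) {
  channels <- lapply(channels, function(x) {
    storage.mode(x) <- "integer"
    x
  })
  if (is.null(bitDepth))
    bitDepth <- if (max(vapply(channels, max, 0L)) > 255L) 16L else 8L
  if (!is.null(artifactMask)) {
    if (!is.logical(artifactMask)) {
      am <- artifactMask != 0
      dim(am) <- dim(artifactMask)
      artifactMask <- am
    }
  }
  new("SlideImage", channels = channels, pixelSize = pixelSize,
      artifactMask = artifactMask, imageId = as.character(imageId),
      bitDepth = as.integer(bitDepth))
}

#' Read a single-channel grayscale raster from PNG or TIFF
#'
#' PNG is read with \pkg{png} (8-bit assumed unless the stored samples are
#' only representable at 16 bits); TIFF is read with \pkg{tiff} at its native
#' integer values. A file with more than one colour channel is rejected.
#'
#' @param path file path ending in \code{.png}, \code{.tif} or \code{.tiff}.
#' @return integer matrix with attribute \code{bitDepth} (8 or 16).
#' @export
readChannel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
    if (length(dim(x)) == 3L) {
      if (dim(x)[3L] == 2L) x <- x[, , 1L]  # gray + alpha
      else stop("non-grayscale image (", dim(x)[3L], " channels): ", path)
    }
    v <- x * 255
    if (max(abs(v - round(v))) < 1e-6) {
      out <- round(v); depth <- 8L
    } else {
      out <- round(x * 65535); depth <- 16L
    }
  } else if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(x)) == 3L)
      stop("non-grayscale image (", dim(x)[3L], " channels): ", path)
    bps <- attr(x, "bits.per.sample")
    depth <- if (!is.null(bps) && bps > 8) 16L else 8L
    out <- x
  } else stop("unsupported image format: ", path)
  storage.mode(out) <- "integer"
  attr(out, "bitDepth") <- depth
  out
}

#' Write a single-channel grayscale raster
#'
#' 8-bit rasters are written as PNG or TIFF by extension; 16-bit rasters must
#' go to TIFF (the PNG writer used here emits 8-bit samples). Written and
#' re-read rasters are bit-exact.
#'
#' @param x integer matrix of intensities.
#' @param path output path (\code{.png}, \code{.tif}, \code{.tiff}).
#' @param bitDepth 8 or 16.
#' @return \code{path}, invisibly.
#' @export
writeChannel <- function(x, path, bitDepth = 8L) {
  ext <- tolower(tools::file_ext(path))
  if (bitDepth == 8L) {
    if (ext == "png") png::writePNG(x / 255, path)
    else if (ext %in% c("tif", "tiff"))
      tiff::writeTIFF(x / 255, path, bits.per.sample = 8L)
    else stop("unsupported image format: ", path)
  } else if (bitDepth == 16L) {
    if (!ext %in% c("tif", "tiff"))
      stop("16-bit rasters must be written as TIFF: ", path)
    tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  } else stop("bitDepth must be 8 or 16")
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are PNG rasters in which any nonzero pixel is set.
#'
#' @param path PNG file path.
#' @return \code{readMask}: a logical matrix.
#' @export
readMask <- function(path) {
  x <- readChannel(path)
  m <- x != 0L
  dim(m) <- dim(x)
  m
}

#' @rdname readMask
#' @param mask logical matrix.
#' @export
writeMask <- function(mask, path) {
  writeChannel(matrix(as.integer(mask) * 255L, nrow(mask), ncol(mask)),
               path, bitDepth = 8L)
}

#' Load a multichannel slide image from per-channel files
#'
#' @param nucleiPath path to the nuclei (DAPI) channel; required.
#' @param markerPath,autofluorescencePath optional paths to the marker
#'   (Ki67/TUNEL) and autofluorescence channels.
#' @param artifactMaskPath optional path to a binary artifact mask
#'   (nonzero = excluded).
#' @param pixelSize pixel edge length in micrometres (default 0.325).
#' @param imageId identifier; defaults to the nuclei file name.
#' @return a validated \linkS4class{SlideImage}. All channels must share one
#'   bit depth and one set of dimensions; mismatches are hard errors naming
#'   both shapes.
#' @export
readSlideImage <- function(nucleiPath, markerPath = NULL,
                           autofluorescencePath = NULL,
                           artifactMaskPath = NULL,
                           pixelSize = 0.325, imageId = NULL) {
  paths <- c(nuclei = nucleiPath, marker = markerPath,
             autofluorescence = autofluorescencePath)
  paths <- paths[!is.na(paths) & nzchar(paths)]
  channels <- lapply(paths, readChannel)
  depths <- vapply(channels, attr, 0L, "bitDepth")
  depth <- max(depths)
  if (depth == 16L && any(depths == 8L))
    channels[depths == 8L] <- lapply(channels[depths == 8L], function(x) x * 257L)
  mask <- NULL
  if (!is.null(artifactMaskPath) && !is.na(artifactMaskPath) &&
      nzchar(artifactMaskPath))
    mask <- readMask(artifactMaskPath)
  if (is.null(imageId))
    imageId <- tools::file_path_sans_ext(basename(nucleiPath))
  SlideImage(channels, pixelSize = pixelSize, artifactMask = mask,
             imageId = imageId, bitDepth = depth)
}

#' Zero out artifact-excluded pixels
#'
#' Pixels flagged by the artifact mask (hand-drawn exclusions of tissue
#' overlaps, air bubbles, dirt, blooming and similar) are set to zero
#' intensity in every channel. The mask itself is retained so the excluded
#' area can be subtracted from downstream denominators. Idempotent; an image
#' without an artifact mask is returned unchanged.
#'
#' @param image a \linkS4class{SlideImage}.
#' @return the masked \linkS4class{SlideImage}.
#' @export
applyArtifactMask <- function(image) {
  stopifnot(is(image, "SlideImage"))
  if (is.null(image@artifactMask)) return(image)
  excl <- image@artifactMask
  image@channels <- lapply(image@channels, function(x) {
    x[excl] <- 0L
    x
  })
  validObject(image)
  image
}

#' Number of artifact-excluded pixels
#'
#' @param image a \linkS4class{SlideImage}.
#' @return integer pixel count (0 when no artifact mask is attached).
#' @export
excludedArea <- function(image) {
  if (is.null(image@artifactMask)) 0L else sum(image@artifactMask)
}

.TISSUE_LEVELS    <- c("tumor", "peritumoral")
.CONDITION_LEVELS <- c("untreated", "treated")
.MARKER_LEVELS    <- c("proliferation", "apoptosis")

#' Load the sample sheet driving a batch analysis
#'
#' The sheet is a CSV with columns \code{image_id}, \code{tissue}
#' (tumor | peritumoral), \code{condition} (untreated | treated),
#' \code{slice_id}, \code{marker_kind} (proliferation | apoptosis),
#' \code{nuclei_path}, \code{marker_path}, and optionally
#' \code{autofluorescence_path} and \code{artifact_mask_path}. Relative paths
#' are resolved against the sheet's directory. Group sizes per
#' (tissue, condition) are reported as a message.
#'
#' @param path CSV file path.
#' @param checkPaths verify that every referenced file exists (default TRUE).
#' @return a data.frame of validated rows.
#' @export
readSampleSheet <- function(path, checkPaths = TRUE) {
  sheet <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_id", "tissue", "condition", "slice_id", "marker_kind",
                "nuclei_path", "marker_path")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet lacks required columns: ", paste(missing, collapse = ", "))
  for (opt in c("autofluorescence_path", "artifact_mask_path"))
    if (!opt %in% names(sheet)) sheet[[opt]] <- NA_character_
  if (anyDuplicated(sheet$image_id))
    stop("duplicate image_id in sample sheet: ",
         paste(unique(sheet$image_id[duplicated(sheet$image_id)]), collapse = ", "))
  bad <- setdiff(unique(sheet$tissue), .TISSUE_LEVELS)
  if (length(bad))
    stop("unknown tissue value(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.TISSUE_LEVELS, collapse = ", "))
  bad <- setdiff(unique(sheet$condition), .CONDITION_LEVELS)
  if (length(bad))
    stop("unknown condition value(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.CONDITION_LEVELS, collapse = ", "))
  bad <- setdiff(unique(sheet$marker_kind), .MARKER_LEVELS)
  if (length(bad))
    stop("unknown marker_kind value(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.MARKER_LEVELS, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | !nzchar(p) | grepl("^/", p),
                                p, file.path(base, p))
  for (col in c("nuclei_path", "marker_path", "autofluorescence_path",
                "artifact_mask_path"))
    sheet[[col]] <- resolve(sheet[[col]])
  if (checkPaths) {
    refs <- unlist(sheet[, c("nuclei_path", "marker_path",
                             "autofluorescence_path", "artifact_mask_path")])
    refs <- refs[!is.na(refs) & nzchar(refs)]
    gone <- refs[!file.exists(refs)]
    if (length(gone))
      stop("sample sheet references missing file(s): ",
           paste(unique(gone), collapse = ", "))
  }
  census <- table(tissue = sheet$tissue, condition = sheet$condition)
  message("sample sheet: ", nrow(sheet), " images; group sizes: ",
          paste(sprintf("%s/%s=%d",
                        rep(rownames(census), ncol(census)),
                        rep(colnames(census), each = nrow(census)),
                        as.vector(census)),
                collapse = ", "))
  sheet
}
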