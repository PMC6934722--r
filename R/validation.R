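#' Build a segmentation bundle from manually drawn observer masks
#'
#' Observer masks enter the same counting path as automatic masks: the marker
#' mask is multiplied with the nuclei mask and cleared of small segments
#' exactly as in [segmentImage()], so any manual/automatic divergence comes
#' from the masks, never from the code path. Masks not supplied are treated
#' as empty.
#'
#' @param masks named list with any subset of \code{tissue}, \code{nuclei},
#'   \code{marker} logical matrices (equal dimensions).
#' @param imageId image identifier.
#' @param maxSpeckSize,connectivity as in [segmentImage()].
#' @return a \linkS4class{SegmentationBundle}.
#' @export
observerBundle <- function(masks, imageId = "manual", maxSpeckSize = 20L,
                           connectivity = 8L) {
  given <- masks[!vapply(masks, is.null, TRUE)]
  if (length(given) == 0L) stop("no observer masks supplied")
  d <- dim(given[[1L]])
  get <- function(nm) if (is.null(masks[[nm]])) matrix(FALSE, d[1L], d[2L])
                      else masks[[nm]]
  nuc <- get("nuclei")
  markerNuc <- restrictToNuclei(get("marker"), nuc)
  markerNuc <- clearSmallSegments(markerNuc, maxSpeckSize, connectivity)
  new("SegmentationBundle",
      tissue = get("tissue"), nuclei = nuc, marker = get("marker"),
      markerInNuclei = markerNuc,
      thresholds = list(tissue = NULL, nuclei = NULL, marker = NULL),
      imageId = as.character(imageId), excludedAreaPx = 0L,
      warnings = character(0))
}

#' Average independent observers' measurements for one image
#'
#' Each observer's mask set is quantified with the automatic counting rules
#' ([observerBundle()] + [quantifyBundle()]); the per-observer areas are then
#' arithmetic-averaged and the ratios recomputed from the averaged areas —
#' the manual-verification convention of the pipeline.
#'
#' @param observerSets list of observer mask sets, each a named list with
#'   elements \code{observer_id} and \code{masks} (as in [observerBundle()]).
#' @param imageId image identifier.
#' @param maxSpeckSize,connectivity as in [segmentImage()].
#' @return one-row data.frame of manual measurements (mean areas, recomputed
#'   ratios, number of observers).
#' @export
averageObservers <- function(observerSets, imageId = "image",
                             maxSpeckSize = 20L, connectivity = 8L) {
  if (length(observerSets) == 0L)
    stop("no observers for image '", imageId, "'")
  recs <- do.call(rbind, lapply(observerSets, function(o) {
    quantifyBundle(observerBundle(o$masks, imageId = imageId,
                                  maxSpeckSize = maxSpeckSize,
                                  connectivity = connectivity))
  }))
  tissueArea <- mean(recs$tissue_area_px)
  nucleiArea <- mean(recs$nuclei_area_px)
  markerArea <- mean(recs$marker_in_nuclei_area_px)
  data.frame(
    image_id = imageId, n_observers = nrow(recs),
    tissue_area_px = tissueArea, nuclei_area_px = nucleiArea,
    marker_in_nuclei_area_px = markerArea,
    ratio_marker_per_nuclei =
      if (nucleiArea > 0) markerArea / nucleiArea else NA_real_,
    ratio_nuclei_per_tissue =
      if (tissueArea > 0) nucleiArea / tissueArea else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Correlate manual and automatic measurements
#'
#' Pairs manual and automatic values strictly by \code{image_id} and reports,
#' per quantity, Spearman's rank correlation coefficient with its p-value
#' together with the squared Pearson (linear) correlation coefficient, plus
#' the direction of systematic bias (sign of the median paired difference,
#' manual minus automatic). Both coefficients are reported because rank
#' correlation is the testing convention while R-squared is the customary
#' reporting scale for this comparison.
#'
#' @param manual,automatic data.frames carrying \code{image_id} and the
#'   quantity columns.
#' @param quantities columns to correlate (default: the three segmented
#'   areas).
#' @return data.frame with one row per quantity: \code{n}, \code{spearman_rho},
#'   \code{spearman_p}, \code{pearson_r2}, \code{bias_direction}.
#' @export
correlateManualAutomatic <- function(manual, automatic,
                                     quantities = c("tissue_area_px",
                                                    "nuclei_area_px",
                                                    "marker_in_nuclei_area_px")) {
  merged <- merge(manual, automatic, by = "image_id",
                  suffixes = c("_manual", "_auto"))
  if (nrow(merged) < 3L)
    stop("need at least 3 paired images; got ", nrow(merged))
  out <- lapply(quantities, function(q) {
    x <- merged[[paste0(q, "_manual")]]
    y <- merged[[paste0(q, "_auto")]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L)
      stop("fewer than 3 finite pairs for ", q)
    sp <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    r <- stats::cor(x, y, method = "pearson")
    diffs <- x - y
    data.frame(
      quantity = q, n = length(x),
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      pearson_r2 = r^2,
      bias_direction = sign(stats::median(diffs)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
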