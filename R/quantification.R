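#' Per-image area measurements and ratios
#'
#' Counts the pixel areas of the tissue, nuclei and nuclear-restricted marker
#' masks (artifact-excluded pixels never enter any mask) and computes the two
#' headline ratios: marker-positive nuclear area per nuclear area (the
#' proliferation or apoptosis ratio) and nuclear area per total tissue area.
#' Zero denominators yield \code{NA} ratios with a flag, never errors.
#' Nuclei pixels falling outside the smoothed tissue mask are not clipped;
#' the discrepancy is reported in \code{nuclei_outside_tissue_px}.
#'
#' @param bundle a \linkS4class{SegmentationBundle}.
#' @param row optional one-row data.frame (or named list) with sample-sheet
#'   annotations \code{image_id}, \code{tissue}, \code{condition},
#'   \code{slice_id}, \code{marker_kind}.
#' @param pixelSizeUm pixel edge length in micrometres (default 0.325),
#'   carried into the record so areas can be converted to um^2.
#' @return a one-row data.frame (the quantification record).
#' @export
quantifyBundle <- function(bundle, row = NULL, pixelSizeUm = 0.325) {
  stopifnot(is(bundle, "SegmentationBundle"))
  tissueArea <- sum(bundle@tissue)
  nucleiArea <- sum(bundle@nuclei)
  markerArea <- sum(bundle@markerInNuclei)
  ann <- list(image_id = bundle@imageId, tissue = NA_character_,
              condition = NA_character_, slice_id = NA_character_,
              marker_kind = NA_character_)
  if (!is.null(row))
    for (f in names(ann)) if (!is.null(row[[f]])) ann[[f]] <- as.character(row[[f]])
  data.frame(
    image_id = ann$image_id, tissue = ann$tissue, condition = ann$condition,
    slice_id = ann$slice_id, marker_kind = ann$marker_kind,
    tissue_area_px = tissueArea,
    nuclei_area_px = nucleiArea,
    marker_in_nuclei_area_px = markerArea,
    excluded_area_px = bundle@excludedAreaPx,
    nuclei_outside_tissue_px = sum(bundle@nuclei & !bundle@tissue),
    ratio_marker_per_nuclei =
      if (nucleiArea > 0) markerArea / nucleiArea else NA_real_,
    ratio_nuclei_per_tissue =
      if (tissueArea > 0) nucleiArea / tissueArea else NA_real_,
    ratio_undefined = nucleiArea == 0 || tissueArea == 0,
    pixel_size_um = pixelSizeUm,
    stringsAsFactors = FALSE
  )
}

#' Average ratios over sections of the same tissue slice
#'
#' For the apoptosis analysis, section-level results are averaged for all
#' sections originating from the same tissue slice (arithmetic mean of each
#' ratio per \code{slice_id}; undefined ratios are dropped from the mean and
#' the flag is propagated).
#'
#' @param records data.frame of quantification records sharing one
#'   \code{marker_kind}.
#' @return data.frame with one row per slice: group labels, mean ratios and
#'   the number of sections aggregated.
#' @export
aggregatePerSlice <- function(records) {
  stopifnot(nrow(records) > 0)
  if (length(unique(records$marker_kind)) > 1L)
    stop("records mix marker kinds; aggregate each marker separately")
  parts <- split(records, records$slice_id)
  out <- lapply(parts, function(g) {
    if (nrow(g) == 0L) return(NULL)
    meanDefined <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    data.frame(
      slice_id = g$slice_id[1L], tissue = g$tissue[1L],
      condition = g$condition[1L], marker_kind = g$marker_kind[1L],
      n_sections = nrow(g),
      ratio_marker_per_nuclei = meanDefined(g$ratio_marker_per_nuclei),
      ratio_nuclei_per_tissue = meanDefined(g$ratio_nuclei_per_tissue),
      ratio_undefined = any(g$ratio_undefined),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Long-format results table with group summaries
#'
#' Attaches a (tissue, condition) group label to every record and summarises
#' each quantity per group as median and interquartile range, the reporting
#' convention of the pipeline.
#'
#' @param records data.frame of per-image (or, for apoptosis, per-slice)
#'   quantification records.
#' @param quantities columns to summarise.
#' @return \code{list(table, summary)}: the labelled long table and the
#'   per-group median/IQR block.
#' @export
groupTable <- function(records,
                       quantities = c("ratio_marker_per_nuclei",
                                      "ratio_nuclei_per_tissue")) {
  stopifnot(nrow(records) > 0)
  records$group <- paste(records$tissue, records$condition, sep = "_")
  quantities <- intersect(quantities, names(records))
  rows <- list()
  for (q in quantities) {
    for (g in unique(records$group)) {
      v <- records[[q]][records$group == g]
      v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, group = g, n = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        iqr = if (length(v)) stats::IQR(v) else NA_real_,
        q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
        q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  list(table = records, summary = do.call(rbind, rows))
}
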