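.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the complete quantification pipeline over a sample sheet
#'
#' For every sheet row: load the channels, apply the artifact mask, optionally
#' unmix, segment into the four masks, and quantify. Apoptosis records are
#' additionally averaged per originating tissue slice. Writes
#' \code{results.csv} (per-image records), \code{summary.csv} (group
#' median/IQR), \code{comparisons.csv} (Kruskal-Wallis + Dunn per quantity),
#' \code{thresholds.json}, per-image mask PNGs, \code{config.json} (the
#' effective configuration plus its hash, referenced by every output through
#' \code{manifest.json}) and \code{run.log}. Missing input files are
#' enumerated before any processing starts. Deterministic: identical inputs
#' and configuration produce byte-identical result tables.
#'
#' @param sampleSheet path to a sample-sheet CSV or an equivalent data.frame
#'   (see [readSampleSheet()]).
#' @param outputDir output directory, created if needed.
#' @param mixing optional mixing matrix (or path to one) for bleedthrough
#'   correction.
#' @param smoothWidth,combine,maxSpeckSize,connectivity,clearNuclei
#'   segmentation tunables, see [segmentImage()].
#' @param alpha significance level for group comparisons (default 0.05).
#' @param adjust Dunn multiplicity adjustment (default "bonferroni").
#' @param writeMasks write per-image mask PNGs (default TRUE).
#' @return invisibly, a list with \code{records}, \code{summary},
#'   \code{comparisons} and the output paths.
#' @export
runPipeline <- function(sampleSheet, outputDir, mixing = NULL,
                        smoothWidth = 5, combine = "max", maxSpeckSize = 20L,
                        connectivity = 8L, clearNuclei = FALSE, alpha = 0.05,
                        adjust = "bonferroni", writeMasks = TRUE) {
  sheet <- if (is.character(sampleSheet)) readSampleSheet(sampleSheet)
           else sampleSheet
  if (is.character(mixing)) mixing <- readMixingMatrix(mixing)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outputDir, "run.log")
  logLines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  # fail-fast validation pass: enumerate all missing files before touching any
  refs <- unlist(sheet[, intersect(c("nuclei_path", "marker_path",
                                     "autofluorescence_path",
                                     "artifact_mask_path"), names(sheet))])
  refs <- refs[!is.na(refs) & nzchar(refs)]
  gone <- unique(refs[!file.exists(refs)])
  if (length(gone))
    stop("missing input file(s): ", paste(gone, collapse = ", "))

  config <- list(smoothWidth = smoothWidth, combine = combine,
                 maxSpeckSize = maxSpeckSize, connectivity = connectivity,
                 clearNuclei = clearNuclei, alpha = alpha, adjust = adjust,
                 mixing = if (is.null(mixing)) NULL else unclass(mixing),
                 nImages = nrow(sheet))
  hash <- .configHash(config)
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(outputDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  if (writeMasks)
    dir.create(file.path(outputDir, "masks"), showWarnings = FALSE)
  records <- list()
  thresholdLog <- list()
  for (i in seq_len(nrow(sheet))) {
    row <- sheet[i, ]
    img <- readSlideImage(row$nuclei_path, row$marker_path,
                          if (!is.na(row$autofluorescence_path))
                            row$autofluorescence_path else NULL,
                          if (!is.na(row$artifact_mask_path))
                            row$artifact_mask_path else NULL,
                          imageId = row$image_id)
    bundle <- withCallingHandlers(
      segmentImage(img, mixing = mixing, smoothWidth = smoothWidth,
                   combine = combine, maxSpeckSize = maxSpeckSize,
                   connectivity = connectivity, clearNuclei = clearNuclei),
      warning = function(w) {
        note("warning [%s]: %s", row$image_id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    rec <- quantifyBundle(bundle, row, pixelSizeUm = pixelSize(img))
    records[[row$image_id]] <- rec
    thresholdLog[[row$image_id]] <- lapply(bundle@thresholds, function(t)
      if (is.null(t)) NULL
      else list(method = t@method, threshold = t@threshold,
                criterion = t@criterionValue))
    note("image %s: tissue %d px, nuclei %d px, marker-in-nuclei %d px%s",
         row$image_id, rec$tissue_area_px, rec$nuclei_area_px,
         rec$marker_in_nuclei_area_px,
         if (rec$ratio_undefined) " (undefined ratio)" else "")
    if (writeMasks) {
      for (m in c("tissue", "nuclei", "marker", "markerInNuclei"))
        writeMask(getMask(bundle, m),
                  file.path(outputDir, "masks",
                            sprintf("%s_%s.png", row$image_id, m)))
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  # apoptosis records are averaged per originating tissue slice
  analysed <- records
  if (any(records$marker_kind == "apoptosis", na.rm = TRUE)) {
    apo <- aggregatePerSlice(records[records$marker_kind == "apoptosis", ])
    note("apoptosis: %d sections averaged into %d slices",
         sum(records$marker_kind == "apoptosis"), nrow(apo))
    other <- records[records$marker_kind != "apoptosis", ]
    core <- c("tissue", "condition", "marker_kind",
              "ratio_marker_per_nuclei", "ratio_nuclei_per_tissue",
              "ratio_undefined")
    analysed <- if (nrow(other)) rbind(other[, core], apo[, core]) else apo
  }

  gt <- groupTable(analysed)
  utils::write.csv(records, file.path(outputDir, "results.csv"),
                   row.names = FALSE)
  utils::write.csv(gt$summary, file.path(outputDir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(thresholdLog, file.path(outputDir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  comparisons <- NULL
  sizes <- table(gt$table$group)
  if (sum(sizes >= 2L) >= 2L) {
    comp <- lapply(c("ratio_marker_per_nuclei", "ratio_nuclei_per_tissue"),
                   function(q) {
      gc <- compareGroups(gt$table, q, alpha = alpha, adjust = adjust)
      note("%s: Kruskal-Wallis chi-sq %.4g (df %d), p = %.4g",
           q, gc$statistic, gc$df, gc$p_value)
      base <- data.frame(quantity = q, test = "kruskal-wallis",
                         group1 = NA_character_, group2 = NA_character_,
                         statistic = gc$statistic, p = gc$p_value,
                         p_adjusted = NA_real_,
                         significant = gc$significant,
                         stringsAsFactors = FALSE)
      if (!is.null(gc$dunn))
        base <- rbind(base, data.frame(
          quantity = q, test = "dunn", group1 = gc$dunn$group1,
          group2 = gc$dunn$group2, statistic = gc$dunn$z, p = gc$dunn$p,
          p_adjusted = gc$dunn$p_adjusted,
          significant = gc$dunn$p_adjusted < alpha,
          stringsAsFactors = FALSE))
      base
    })
    comparisons <- do.call(rbind, comp)
    utils::write.csv(comparisons, file.path(outputDir, "comparisons.csv"),
                     row.names = FALSE)
  } else {
    note("fewer than 2 usable groups; group comparison skipped")
  }

  outputs <- list.files(outputDir, recursive = TRUE)
  jsonlite::write_json(
    list(config_hash = hash, outputs = setdiff(outputs, "manifest.json")),
    file.path(outputDir, "manifest.json"), auto_unbox = TRUE)
  writeLines(logLines, logFile)
  invisible(list(records = records, summary = gt$summary,
                 comparisons = comparisons, outputDir = outputDir,
                 configHash = hash))
}
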