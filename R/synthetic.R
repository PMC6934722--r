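#' Construct a synthetic-scene specification
#'
#' Defaults describe the desk-scale reference condition used throughout the test
#' suite: a 512x512 8-bit slide at 0.325 um/px carrying 200 clustered
#' elliptical nuclei of 5-9 px radius (3.3-5.9 um, i.e. 6-12 um nuclear
#' diameters), a marker-positive subpopulation, diffuse autofluorescence over
#' the tissue region, blooming halos, sub-nuclear specks, optional
#' inter-channel bleedthrough, and additive Gaussian noise with standard
#' deviation 25.5 (10% of the 8-bit dynamic range).
#'
#' @param dims image dimensions (rows, columns).
#' @param nNuclei number of nuclei.
#' @param radiusRange nucleus radius range in pixels.
#' @param positiveFraction fraction of marker-positive nuclei in [0, 1].
#' @param background,autofluorescence,nucleusIntensity,markerIntensity 8-bit
#'   intensity levels.
#' @param noiseSD additive Gaussian noise SD.
#' @param bleedthrough square named mixing matrix (identity = none).
#' @param haloWidth blooming halo width in pixels.
#' @param haloFraction halo intensity as a fraction of the parent signal.
#' @param speckCount number of marker-channel specks.
#' @param speckSizeRange speck area range in pixels, within [1, 20].
#' @param pixelSize physical pixel size in micrometres.
#' @return a validated \linkS4class{SceneSpec}.
#' @export
sceneSpec <- function(dims = c(512L, 512L), nNuclei = 200L,
                      radiusRange = c(5, 9), positiveFraction = 0.3,
                      background = 8, autofluorescence = 110,
                      nucleusIntensity = 190, markerIntensity = 200,
                      noiseSD = 25.5, bleedthrough = NULL,
                      haloWidth = 2, haloFraction = 0.35,
                      speckCount = 25L, speckSizeRange = c(1, 12),
                      pixelSize = 0.325) {
  if (is.null(bleedthrough)) {
    bleedthrough <- diag(3)
    dimnames(bleedthrough) <- list(c("nuclei", "marker", "autofluorescence"),
                                   c("nuclei", "marker", "autofluorescence"))
  }
  new("SceneSpec", dims = as.integer(dims), nNuclei = as.integer(nNuclei),
      radiusRange = as.numeric(radiusRange),
      positiveFraction = positiveFraction, background = background,
      autofluorescence = autofluorescence,
      nucleusIntensity = nucleusIntensity, markerIntensity = markerIntensity,
      noiseSD = noiseSD, bleedthrough = bleedthrough,
      haloWidth = haloWidth, haloFraction = haloFraction,
      speckCount = as.integer(speckCount),
      speckSizeRange = as.numeric(speckSizeRange), pixelSize = pixelSize)
}

# Elliptical tissue region: union of a few random ellipses kept inside the
# frame, covering roughly half to two thirds of it.
.tissueRegion <- function(nr, nc) {
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  region <- matrix(FALSE, nr, nc)
  for (i in seq_len(3L)) {
    cy <- stats::runif(1, 0.3, 0.7) * nr
    cx <- stats::runif(1, 0.3, 0.7) * nc
    a <- stats::runif(1, 0.22, 0.34) * nr
    b <- stats::runif(1, 0.22, 0.34) * nc
    region <- region | (((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1)
  }
  region
}

# Pixel indices of an ellipse with semi-axes a, b and orientation theta,
# clipped to the frame.
.ellipsePixels <- function(cy, cx, a, b, theta, nr, nc) {
  ext <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, floor(cy - ext)); r1 <- min(nr, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(nc, ceiling(cx + ext))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  (rep(cc, each = length(rr))[idx] - 1L) * nr + rep(rr, length(cc))[idx]
}

# Connected blob of exactly `size` pixels grown by random neighbour accretion.
.growBlob <- function(start, size, nr, nc) {
  cells <- start
  frontier <- start
  while (length(cells) < size && length(frontier) > 0L) {
    seed <- frontier[sample.int(length(frontier), 1L)]
    r <- (seed - 1L) %% nr + 1L
    co <- (seed - 1L) %/% nr + 1L
    nb <- c(if (r > 1L) seed - 1L, if (r < nr) seed + 1L,
            if (co > 1L) seed - nr, if (co < nc) seed + nr)
    nb <- setdiff(nb, cells)
    if (length(nb) == 0L) {
      frontier <- setdiff(frontier, seed)
      next
    }
    cells <- c(cells, nb[sample.int(length(nb), 1L)])
    frontier <- unique(c(frontier, cells[length(cells)]))
  }
  cells
}

.dilateMask <- function(mask, width) {
  if (width <= 0 || !any(mask)) return(mask)
  brush <- EBImage::makeBrush(2L * ceiling(width) + 1L, shape = "disc")
  out <- EBImage::dilate(mask * 1, brush) > 0
  dim(out) <- dim(mask)
  out
}

#' Generate one synthetic multichannel slide with ground truth
#'
#' Places non-overlapping elliptical nuclei, spatially clustered inside a
#' simulated tissue region; marks exactly
#' \code{floor(positiveFraction * nNuclei)} of them as marker-positive;
#' renders the three channels (DAPI-like nuclei, Ki67/TUNEL-like marker,
#' diffuse autofluorescence) with blooming halos and sub-nuclear specks;
#' applies the bleedthrough matrix; and adds clipped Gaussian noise. The
#' ground truth records the pre-noise, pre-mixing geometry so segmentation
#' accuracy is measurable against an uncorrupted reference. Deterministic
#' given a seed.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param seed optional integer seed; when \code{NULL} the current RNG state
#'   is used (so one seed can drive a whole cohort).
#' @param imageId identifier of the generated image.
#' @return \code{list(image, truth)} where \code{image} is a
#'   \linkS4class{SlideImage} and \code{truth} a list with logical masks
#'   \code{tissue}, \code{nuclei}, \code{marker}, the per-nucleus label
#'   matrix \code{labels}, the nucleus \code{centers} data.frame, the indices
#'   of \code{positive} nuclei, the realised \code{positiveFraction}, and
#'   pixel \code{areas}.
#' @export
generateSlide <- function(spec = sceneSpec(), seed = NULL, imageId = "synthetic") {
  stopifnot(is(spec, "SceneSpec"))
  if (!is.null(seed)) set.seed(seed)
  nr <- spec@dims[1L]; nc <- spec@dims[2L]
  npix <- nr * nc
  tissue <- .tissueRegion(nr, nc)

  n <- spec@nNuclei
  labels <- matrix(0L, nr, nc)
  occupied <- matrix(FALSE, nr, nc)
  centers <- data.frame(row = numeric(0), col = numeric(0), radius = numeric(0))
  if (n > 0L) {
    tissueIdx <- which(tissue)
    if (length(tissueIdx) == 0L) stop("tissue region is empty")
    nClusters <- max(1L, round(n / 25))
    clusterIdx <- tissueIdx[sample.int(length(tissueIdx), nClusters)]
    clusterR <- (clusterIdx - 1L) %% nr + 1L
    clusterC <- (clusterIdx - 1L) %/% nr + 1L
    spread <- min(nr, nc) / 6
    placed <- 0L
    attempts <- 0L
    maxAttempts <- 200L * n
    cRow <- cCol <- cRad <- numeric(n)
    while (placed < n && attempts < maxAttempts) {
      attempts <- attempts + 1L
      # mostly cluster-centred proposals, with a uniform share so dense
      # clusters cannot make a feasible packing stall
      if (stats::runif(1) < 0.75) {
        k <- sample.int(nClusters, 1L)
        cy <- stats::rnorm(1, clusterR[k], spread)
        cx <- stats::rnorm(1, clusterC[k], spread)
      } else {
        u <- tissueIdx[sample.int(length(tissueIdx), 1L)]
        cy <- (u - 1L) %% nr + 1L
        cx <- (u - 1L) %/% nr + 1L
      }
      r <- stats::runif(1, spec@radiusRange[1L], spec@radiusRange[2L])
      if (cy < r + 2 || cy > nr - r - 1 || cx < r + 2 || cx > nc - r - 1) next
      if (!tissue[round(cy), round(cx)]) next
      # cheap bounding-box pre-check before rasterising the clearance ellipse
      ext <- ceiling(r * 1.18 + 1.5)
      box <- occupied[max(1, floor(cy - ext)):min(nr, ceiling(cy + ext)),
                      max(1, floor(cx - ext)):min(nc, ceiling(cx + ext))]
      stretch <- stats::runif(1, 0.85, 1.18)
      a <- r * stretch; b <- r / stretch
      theta <- stats::runif(1, 0, pi)
      if (any(box)) {
        # require a 1-px clearance so neighbouring nuclei stay separable
        halo <- .ellipsePixels(cy, cx, a + 1.5, b + 1.5, theta, nr, nc)
        if (any(occupied[halo])) next
      } else {
        halo <- .ellipsePixels(cy, cx, a + 1.5, b + 1.5, theta, nr, nc)
      }
      px <- .ellipsePixels(cy, cx, a, b, theta, nr, nc)
      if (length(px) == 0L) next
      placed <- placed + 1L
      labels[px] <- placed
      occupied[halo] <- TRUE
      cRow[placed] <- cy; cCol[placed] <- cx; cRad[placed] <- r
    }
    centers <- data.frame(row = cRow[seq_len(placed)],
                          col = cCol[seq_len(placed)],
                          radius = cRad[seq_len(placed)])
    if (placed < n)
      stop("infeasible packing: placed ", placed, " of ", n,
           " nuclei after ", maxAttempts, " attempts")
  }
  nucleiTruth <- labels > 0L
  nPos <- floor(spec@positiveFraction * n)
  positive <- if (nPos > 0L) sort(sample.int(n, nPos)) else integer(0)
  markerTruth <- matrix(labels %in% positive & nucleiTruth, nr, nc)

  haloN <- .dilateMask(nucleiTruth, spec@haloWidth) & !nucleiTruth
  haloM <- .dilateMask(markerTruth, spec@haloWidth) & !markerTruth

  chNuclei <- matrix(spec@background, nr, nc)
  chNuclei[haloN] <- spec@background + spec@haloFraction * spec@nucleusIntensity
  chNuclei[nucleiTruth] <- spec@nucleusIntensity
  chMarker <- matrix(spec@background / 2, nr, nc)
  chMarker[haloM] <- spec@background / 2 + spec@haloFraction * spec@markerIntensity
  chMarker[markerTruth] <- spec@markerIntensity
  chAuto <- matrix(spec@background, nr, nc)
  chAuto[tissue] <- spec@autofluorescence

  # fluorescent specks in the marker channel, inside and outside nuclei;
  # kept 1 px apart so no two specks merge past the clearable size
  if (spec@speckCount > 0L) {
    speckOcc <- matrix(FALSE, nr, nc)
    for (s in seq_len(spec@speckCount)) {
      size <- sample(seq(spec@speckSizeRange[1L], spec@speckSizeRange[2L]), 1L)
      for (try in 1:5) {
        start <- sample.int(npix, 1L)
        cells <- .growBlob(start, size, nr, nc)
        rows <- (cells - 1L) %% nr + 1L
        cols <- (cells - 1L) %/% nr + 1L
        clash <- FALSE
        for (dr in -1:1) for (dc in -1:1) {
          rr <- pmin(pmax(rows + dr, 1L), nr)
          cc <- pmin(pmax(cols + dc, 1L), nc)
          if (any(speckOcc[cbind(rr, cc)])) { clash <- TRUE; break }
        }
        if (!clash) {
          speckOcc[cells] <- TRUE
          chMarker[cells] <- pmax(chMarker[cells], 0.85 * spec@markerIntensity)
          break
        }
      }
    }
  }

  pure <- list(nuclei = chNuclei, marker = chMarker, autofluorescence = chAuto)
  identityMix <- all(spec@bleedthrough == diag(nrow(spec@bleedthrough)))
  mixed <- if (identityMix) lapply(pure, round)
           else mixChannels(pure, spec@bleedthrough, maxIntensity = 255L)
  channels <- lapply(mixed, function(x) {
    if (spec@noiseSD > 0)
      x <- x + stats::rnorm(npix, 0, spec@noiseSD)
    x <- matrix(pmin(pmax(round(x), 0), 255), nr, nc)
    storage.mode(x) <- "integer"
    x
  })

  image <- SlideImage(channels, pixelSize = spec@pixelSize,
                      imageId = imageId, bitDepth = 8L)
  truth <- list(
    tissue = tissue, nuclei = nucleiTruth, marker = markerTruth,
    labels = labels, centers = centers, positive = positive,
    positiveFraction = if (n > 0L) nPos / n else NA_real_,
    areas = c(tissue = sum(tissue), nuclei = sum(nucleiTruth),
              marker = sum(markerTruth))
  )
  list(image = image, truth = truth)
}

#' Default four-group cohort design
#'
#' A glioblastoma-resection cohort shape: untreated and treated peritumoral
#' brain and tumor tissue, with a realistic whole-slide image count per group
#' (33/32/13/8) and marker-positive fractions chosen so that tumor tissue
#' proliferates more than peritumoral tissue and treatment lowers both.
#'
#' @return data.frame with columns \code{tissue}, \code{condition},
#'   \code{positive_fraction}, \code{n_images}.
#' @export
defaultCohortGroups <- function() {
  data.frame(
    tissue            = c("peritumoral", "peritumoral", "tumor", "tumor"),
    condition         = c("untreated", "treated", "untreated", "treated"),
    positive_fraction = c(0.25, 0.10, 0.40, 0.15),
    n_images          = c(33L, 32L, 13L, 8L),
    stringsAsFactors  = FALSE
  )
}

#' Generate a synthetic cohort with sample sheet and ground truth
#'
#' One global random generator drives the whole cohort (seeded once from
#' \code{seed}), so a single integer reproduces every image. Sections are
#' assigned to originating slices in runs of \code{sectionsPerSlice},
#' mirroring technical replicates cut from the same tissue slice.
#'
#' @param groups data.frame as from [defaultCohortGroups()].
#' @param spec template \linkS4class{SceneSpec}; each image inherits it with
#'   the group's \code{positive_fraction}.
#' @param seed integer seed for the whole cohort.
#' @param dir output directory; when given, channel PNGs, ground-truth mask
#'   PNGs, \code{sample_sheet.csv} and \code{truth.json} are written and the
#'   sheet rows carry the file paths. When \code{NULL} everything stays in
#'   memory.
#' @param markerKind \code{"proliferation"} or \code{"apoptosis"}.
#' @param sectionsPerSlice sections cut per tissue slice (default 3).
#' @return \code{list(sheet, images, truth)}; \code{images} is \code{NULL}
#'   when \code{dir} is given (they live on disk).
#' @export
generateCohort <- function(groups = defaultCohortGroups(), spec = sceneSpec(),
                           seed = 1L, dir = NULL,
                           markerKind = c("proliferation", "apoptosis"),
                           sectionsPerSlice = 3L) {
  markerKind <- match.arg(markerKind)
  stopifnot(nrow(groups) >= 2L,
            all(c("tissue", "condition", "positive_fraction",
                  "n_images") %in% names(groups)))
  set.seed(seed)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheetRows <- list()
  images <- list()
  truths <- list()
  for (g in seq_len(nrow(groups))) {
    gspec <- spec
    gspec@positiveFraction <- groups$positive_fraction[g]
    validObject(gspec)
    tag <- paste(groups$tissue[g], groups$condition[g], sep = "_")
    for (i in seq_len(groups$n_images[g])) {
      id <- sprintf("%s_%02d", tag, i)
      sl <- generateSlide(gspec, seed = NULL, imageId = id)
      sliceId <- sprintf("%s_slice%02d", tag,
                         ceiling(i / max(1L, sectionsPerSlice)))
      row <- data.frame(
        image_id = id, tissue = groups$tissue[g],
        condition = groups$condition[g], slice_id = sliceId,
        marker_kind = markerKind,
        nuclei_path = NA_character_, marker_path = NA_character_,
        autofluorescence_path = NA_character_,
        artifact_mask_path = NA_character_,
        true_positive_fraction = sl$truth$positiveFraction,
        stringsAsFactors = FALSE
      )
      if (is.null(dir)) {
        images[[id]] <- sl$image
        truths[[id]] <- sl$truth
      } else {
        paths <- file.path(dir, paste0(id, "_", c("nuclei", "marker",
                                                  "autofluorescence"), ".png"))
        writeChannel(getChannel(sl$image, "nuclei"), paths[1L])
        writeChannel(getChannel(sl$image, "marker"), paths[2L])
        writeChannel(getChannel(sl$image, "autofluorescence"), paths[3L])
        writeMask(sl$truth$nuclei, file.path(dir, paste0(id, "_truth_nuclei.png")))
        writeMask(sl$truth$marker, file.path(dir, paste0(id, "_truth_marker.png")))
        writeMask(sl$truth$tissue, file.path(dir, paste0(id, "_truth_tissue.png")))
        row$nuclei_path <- paths[1L]
        row$marker_path <- paths[2L]
        row$autofluorescence_path <- paths[3L]
        truths[[id]] <- list(areas = sl$truth$areas,
                             positiveFraction = sl$truth$positiveFraction)
      }
      sheetRows[[id]] <- row
    }
  }
  sheet <- do.call(rbind, sheetRows)
  rownames(sheet) <- NULL
  if (!is.null(dir)) {
    utils::write.csv(sheet, file.path(dir, "sample_sheet.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truths, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(sheet = sheet, images = if (is.null(dir)) images else NULL,
       truth = truths)
}
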