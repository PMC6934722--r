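test_that("clearSmallSegments removes exactly the components at the 20/21-px boundary", {
  mask <- matrix(FALSE, 30, 30)
  mask[2:5, 2:6] <- TRUE                    # 20 px: removed
  mask[10:12, 10:16] <- TRUE                # 21 px: kept
  out <- clearSmallSegments(mask, maxSize = 20L)
  expect_equal(sum(out), 21)
  expect_true(all(out[10:12, 10:16]))
  expect_false(any(out[2:5, 2:6]))
  expect_identical(clearSmallSegments(matrix(FALSE, 5, 5)),
                   matrix(FALSE, 5, 5))
})

test_that("component labelling and clearing agree with a flood-fill oracle", {
  set.seed(55)
  for (i in 1:12) {
    mask <- randomMask(40, 40, density = runif(1, 0.15, 0.45))
    for (conn in c(4L, 8L)) {
      labels <- labelComponents(mask, conn)
      oracleSizes <- sort(oracleComponentSizes(mask, conn))
      sizes <- sort(tabulate(labels[labels > 0L]))
      expect_equal(sizes, oracleSizes)
      cleared <- clearSmallSegments(mask, 20L, conn)
      expect_equal(sum(cleared), sum(oracleSizes[oracleSizes > 20]))
      # clearing is idempotent and shrinking
      expect_identical(clearSmallSegments(cleared, 20L, conn), cleared)
      expect_true(all(!cleared | mask))
      surviving <- oracleComponentSizes(cleared, conn)
      if (length(surviving)) expect_true(all(surviving >= 21))
    }
  }
})

test_that("8-connectivity joins diagonal touches that 4-connectivity separates", {
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- mask[2, 2] <- TRUE
  expect_equal(attr(labelComponents(mask, 8L), "nComponents"), 1L)
  expect_equal(attr(labelComponents(mask, 4L), "nComponents"), 2L)
})

test_that("restrictToNuclei is pixelwise multiplication", {
  set.seed(9)
  marker <- randomMask(20, 20)
  nuclei <- randomMask(20, 20)
  expect_identical(restrictToNuclei(marker, matrix(TRUE, 20, 20)), marker)
  expect_identical(restrictToNuclei(marker, !marker), matrix(FALSE, 20, 20))
  sub <- marker & nuclei
  expect_identical(restrictToNuclei(sub, nuclei), sub)   # absorption
  expect_error(restrictToNuclei(marker, matrix(TRUE, 10, 10)), "differ")
})

test_that("tissue mask recovers a solid disk within the smoothing tolerance", {
  nr <- nc <- 201
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disk <- (rows - 101)^2 + (cols - 101)^2 <= 60^2
  ch <- matrix(0L, nr, nc)
  ch[disk] <- 180L
  img <- SlideImage(list(nuclei = ch, marker = matrix(0L, nr, nc)))
  res <- tissueMask(img)
  expect_lt(abs(sum(res$mask) - sum(disk)) / sum(disk), 0.05)
  expect_equal(res$threshold@method, "otsu")

  # artifact mask over half the disk confines the tissue mask
  am <- matrix(FALSE, nr, nc)
  am[, 1:101] <- TRUE
  imgm <- SlideImage(list(nuclei = ch, marker = matrix(0L, nr, nc)),
                     artifactMask = am)
  resm <- tissueMask(imgm)
  expect_false(any(resm$mask[, 1:101]))
  expect_true(any(resm$mask[, 102:nc]))
})

test_that("blank and single-valued channels yield empty masks with warnings", {
  img <- SlideImage(list(nuclei = matrix(0L, 20, 20),
                         marker = matrix(0L, 20, 20)))
  expect_warning(res <- tissueMask(img), "empty mask")
  expect_false(any(res$mask))
  expect_null(res$threshold)
  flat <- SlideImage(list(nuclei = matrix(77L, 20, 20),
                          marker = matrix(0L, 20, 20)))
  expect_warning(resn <- nucleiMask(flat), "degenerate")
  expect_false(any(resn$mask))
})

test_that("bimodal channels binarise to exactly the bright pixels", {
  set.seed(2)
  ch <- matrix(10L, 40, 40)
  bright <- sample(1600, 300)
  ch[bright] <- 200L
  img <- SlideImage(list(nuclei = ch, marker = ch))
  expect_equal(which(nucleiMask(img)$mask), sort(bright))
  expect_equal(which(markerMask(img)$mask), sort(bright))
})

test_that("marker staining outside nuclei survives marker_mask but not restriction", {
  ch <- matrix(5L, 30, 30)
  nuc <- matrix(5L, 30, 30)
  nuc[5:10, 5:10] <- 200L
  ch[20:25, 20:25] <- 200L                 # marker blob outside nuclei
  img <- SlideImage(list(nuclei = nuc, marker = ch))
  mm <- markerMask(img)
  expect_gt(sum(mm$mask), 0)
  b <- segmentImage(img)
  expect_equal(sum(b@markerInNuclei), 0)
})

test_that("segmentImage maintains the subset chain and honours artifact exclusion", {
  set.seed(14)
  sl <- generateSlide(testSpec(), seed = 3)
  am <- matrix(FALSE, 128, 128)
  am[1:30, ] <- TRUE
  img <- SlideImage(sl$image@channels, artifactMask = am,
                    imageId = "masked")
  b <- segmentImage(img)
  expect_true(all(!b@markerInNuclei | b@nuclei))
  expect_true(all(!b@markerInNuclei | b@marker))
  for (m in c("tissue", "nuclei", "marker", "markerInNuclei"))
    expect_false(any(getMask(b, m) & am))
  expect_equal(b@excludedAreaPx, sum(am))
})

test_that("marker-positive component count tracks the programmed positive count", {
  sl <- generateSlide(sceneSpec(dims = c(384L, 384L), nNuclei = 100L,
                                radiusRange = c(4, 7), positiveFraction = 0.3,
                                speckCount = 10L),
                      seed = 8)
  b <- segmentImage(sl$image)
  labels <- labelComponents(b@markerInNuclei, 8L)
  nComp <- attr(labels, "nComponents")
  expect_gte(nComp, 28)
  expect_lte(nComp, 32)
  # zero positive fraction leaves the restricted marker mask empty
  sl0 <- generateSlide(testSpec(positiveFraction = 0, speckCount = 0L), seed = 2)
  b0 <- segmentImage(sl0$image)
  expect_lt(sum(b0@markerInNuclei), 25)    # at most stray noise, no nuclei
})

test_that("raising the positive fraction never shrinks the marker-in-nuclei area", {
  areas <- vapply(c(0.1, 0.3, 0.5, 0.8), function(p) {
    sl <- generateSlide(testSpec(positiveFraction = p, noiseSD = 0,
                                 speckCount = 0L), seed = 77)
    sum(segmentImage(sl$image)@markerInNuclei)
  }, 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("segmentation is deterministic for identical input and config", {
  sl <- generateSlide(testSpec(), seed = 31)
  b1 <- segmentImage(sl$image)
  b2 <- segmentImage(sl$image)
  expect_identical(b1@tissue, b2@tissue)
  expect_identical(b1@markerInNuclei, b2@markerInNuclei)
  expect_identical(thresholdValue(thresholds(b1)$marker),
                   thresholdValue(thresholds(b2)$marker))
})
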