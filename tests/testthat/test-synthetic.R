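test_that("generation is bit-reproducible given a seed", {
  a <- generateSlide(testSpec(), seed = 99)
  b <- generateSlide(testSpec(), seed = 99)
  expect_identical(a$image@channels, b$image@channels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$positive, b$truth$positive)
  c <- generateSlide(testSpec(), seed = 100)
  expect_false(identical(a$image@channels, c$image@channels))
})

test_that("ground truth honours the scene contract", {
  sl <- generateSlide(testSpec(positiveFraction = 0.3), seed = 41)
  tr <- sl$truth
  # marker truth is nested in nuclei truth, which lies inside tissue
  expect_true(all(!tr$marker | tr$nuclei))
  expect_equal(unname(tr$areas["nuclei"]), sum(tr$nuclei))
  expect_equal(unname(tr$areas["marker"]), sum(tr$marker))
  expect_equal(unname(tr$areas["tissue"]), sum(tr$tissue))
  # exactly floor(p * n) positive nuclei
  expect_equal(length(tr$positive), floor(0.3 * 25))
  expect_equal(tr$positiveFraction, floor(0.3 * 25) / 25)
  expect_equal(nrow(tr$centers), 25)
  # nuclei do not touch: every labelled component is one nucleus
  lab <- labelComponents(tr$nuclei, 8L)
  expect_equal(attr(lab, "nComponents"), 25L)
})

test_that("edge cases: no nuclei, full positivity, infeasible packing", {
  empty <- generateSlide(testSpec(nNuclei = 0L), seed = 1)
  expect_equal(sum(empty$truth$nuclei), 0)
  expect_equal(sum(empty$truth$marker), 0)
  expect_equal(length(empty$truth$positive), 0)

  full <- generateSlide(testSpec(positiveFraction = 1), seed = 2)
  expect_identical(full$truth$marker, full$truth$nuclei)

  expect_error(generateSlide(sceneSpec(dims = c(64L, 64L), nNuclei = 500L,
                                       radiusRange = c(5, 9)), seed = 3),
               "infeasible packing")
})

test_that("n = 100, p = 0.3 yields exactly 30 positive nuclei", {
  sl <- generateSlide(sceneSpec(dims = c(384L, 384L), nNuclei = 100L,
                                radiusRange = c(4, 7), positiveFraction = 0.3),
                      seed = 1)
  expect_equal(length(sl$truth$positive), 30)
})

test_that("specks stay within the clearable size range", {
  spec <- testSpec(nNuclei = 0L, noiseSD = 0, speckCount = 15L,
                   speckSizeRange = c(1, 12))
  sl <- generateSlide(spec, seed = 13)
  mk <- getChannel(sl$image, "marker") > 100L
  sizes <- oracleComponentSizes(mk, 4)     # blobs are grown 4-connected
  expect_true(all(sizes <= 20))
  expect_gt(length(sizes), 0)
})

test_that("cohort generation reproduces the requested census and writes a runnable sheet", {
  dir <- withr::local_tempdir()
  groups <- data.frame(
    tissue = c("peritumoral", "tumor"), condition = c("untreated", "untreated"),
    positive_fraction = c(0.2, 0.4), n_images = c(3L, 2L))
  co <- generateCohort(groups, spec = testSpec(), seed = 7, dir = dir)
  expect_equal(nrow(co$sheet), 5)
  expect_equal(sum(co$sheet$tissue == "peritumoral"), 3)
  expect_true(all(file.exists(co$sheet$nuclei_path)))
  expect_true(file.exists(file.path(dir, "sample_sheet.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  reread <- suppressMessages(
    readSampleSheet(file.path(dir, "sample_sheet.csv")))
  expect_equal(nrow(reread), 5)

  # in-memory variant returns the images and matches unbalanced clinical group sizes
  big <- data.frame(
    tissue = c("peritumoral", "peritumoral", "tumor", "tumor"),
    condition = c("untreated", "treated", "untreated", "treated"),
    positive_fraction = 0.1, n_images = c(33L, 32L, 13L, 8L))
  # only the sheet structure matters here; keep the scenes tiny
  co2 <- generateCohort(big[big$n_images <= 13, ],
                        spec = testSpec(nNuclei = 5L), seed = 8)
  expect_equal(nrow(co2$sheet), 21)
  expect_equal(length(co2$images), 21)
})

test_that("cohorts assign sections to slices in runs", {
  groups <- data.frame(tissue = c("tumor", "peritumoral"),
                       condition = "untreated",
                       positive_fraction = 0.3, n_images = c(6L, 0L))
  co <- generateCohort(groups, spec = testSpec(nNuclei = 8L), seed = 5,
                       sectionsPerSlice = 3L)
  expect_equal(length(unique(co$sheet$slice_id)), 2)
  expect_equal(as.vector(table(co$sheet$slice_id)), c(3L, 3L))
})

test_that("bleedthrough hurts uncorrected ratios and unmixing repairs them", {
  m <- matrix(c(1, 0.3, 0, 0.3, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  dimnames(m) <- list(c("nuclei", "marker", "autofluorescence"),
                      c("nuclei", "marker", "autofluorescence"))
  spec0 <- sceneSpec(dims = c(256L, 256L), nNuclei = 60L, radiusRange = c(4, 7),
                     positiveFraction = 0.3)
  specM <- sceneSpec(dims = c(256L, 256L), nNuclei = 60L, radiusRange = c(4, 7),
                     positiveFraction = 0.3, bleedthrough = m)
  ratio <- function(img, mixing = NULL)
    quantifyBundle(segmentImage(img, mixing = mixing))$ratio_marker_per_nuclei
  clean <- mixed <- corrected <- numeric(3)
  for (s in 1:3) {
    clean[s] <- ratio(generateSlide(spec0, seed = s)$image)
    img <- generateSlide(specM, seed = s)$image
    mixed[s] <- ratio(img)
    corrected[s] <- ratio(img, mixing = m)
  }
  expect_lt(abs(mean(corrected) - mean(clean)), 0.02)
  expect_gt(abs(mean(mixed) - mean(clean)), abs(mean(corrected) - mean(clean)))
})
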