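test_that("channel rasters round-trip bit-exactly through PNG and TIFF", {
  set.seed(3)
  x8 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  storage.mode(x8) <- "integer"
  f <- withr::local_tempfile(fileext = ".png")
  writeChannel(x8, f)
  y <- readChannel(f)
  expect_identical(unname(y[, ]), unname(x8), ignore_attr = TRUE)
  expect_equal(attr(y, "bitDepth"), 8L)

  x16 <- matrix(sample(0:65535, 400, replace = TRUE), 20, 20)
  storage.mode(x16) <- "integer"
  ft <- withr::local_tempfile(fileext = ".tif")
  writeChannel(x16, ft, bitDepth = 16L)
  y16 <- readChannel(ft)
  expect_equal(unname(as.vector(y16)), as.vector(x16))
  expect_equal(attr(y16, "bitDepth"), 16L)

  m <- matrix(runif(400) < 0.4, 20, 20)
  fm <- withr::local_tempfile(fileext = ".png")
  writeMask(m, fm)
  expect_identical(readMask(fm), m)
})

test_that("readSlideImage loads equal-dimension grayscale channels", {
  dir <- withr::local_tempdir()
  mk <- function(name, v) {
    f <- file.path(dir, name)
    writeChannel(matrix(v, 100, 100), f)
    f
  }
  img <- readSlideImage(mk("n.png", 120L), mk("m.png", 40L), mk("a.png", 60L),
                        pixelSize = 0.325)
  expect_s4_class(img, "SlideImage")
  expect_equal(dim(img), c(100L, 100L))
  expect_setequal(channelNames(img), c("nuclei", "marker", "autofluorescence"))
  expect_equal(pixelSize(img), 0.325)

  # mismatched dimensions are a hard error naming both shapes
  bad <- file.path(dir, "bad.png")
  writeChannel(matrix(0L, 101, 100), bad)
  expect_error(readSlideImage(mk("n2.png", 1L), bad), "101")

  # an all-zero artifact mask excludes nothing
  am <- file.path(dir, "mask0.png")
  writeMask(matrix(FALSE, 100, 100), am)
  img0 <- readSlideImage(mk("n3.png", 5L), artifactMaskPath = am)
  expect_equal(excludedArea(img0), 0L)
})

test_that("non-grayscale input is rejected", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(300), dim = c(10, 10, 3)), f)
  expect_error(readChannel(f), "non-grayscale")
})

test_that("applyArtifactMask zeroes flagged pixels in every channel, idempotently", {
  ch <- list(nuclei = matrix(100L, 10, 10), marker = matrix(50L, 10, 10))
  am <- matrix(FALSE, 10, 10)
  am[1, 1:10] <- TRUE
  img <- SlideImage(ch, artifactMask = am)
  out <- applyArtifactMask(img)
  expect_equal(sum(getChannel(out, "nuclei") == 0L), 10)
  expect_equal(sum(getChannel(out, "marker") == 0L), 10)
  expect_equal(excludedArea(out), 10L)
  expect_identical(applyArtifactMask(out)@channels, out@channels)

  # saturation: mask covering everything blanks all channels
  full <- SlideImage(ch, artifactMask = matrix(TRUE, 10, 10))
  expect_true(all(getChannel(applyArtifactMask(full), "nuclei") == 0L))

  # no mask: unchanged
  plain <- SlideImage(ch)
  expect_identical(applyArtifactMask(plain)@channels, plain@channels)
})

test_that("sample sheets validate tokens, ids and the group census", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "img.png")
  writeChannel(matrix(0L, 4, 4), f)
  mkSheet <- function(df, name = "sheet.csv") {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    p
  }
  base <- data.frame(
    image_id = paste0("im", 1:4),
    tissue = c("tumor", "tumor", "peritumoral", "peritumoral"),
    condition = c("untreated", "treated", "untreated", "treated"),
    slice_id = "s1", marker_kind = "proliferation",
    nuclei_path = "img.png", marker_path = "img.png",
    stringsAsFactors = FALSE
  )
  sheet <- suppressMessages(readSampleSheet(mkSheet(base)))
  expect_equal(nrow(sheet), 4)
  expect_equal(as.vector(table(sheet$tissue, sheet$condition)), rep(1L, 4))

  dup <- base; dup$image_id <- "same"
  expect_error(suppressMessages(readSampleSheet(mkSheet(dup, "dup.csv"))),
               "duplicate image_id")

  bad <- base; bad$tissue[1] <- "liver"
  expect_error(suppressMessages(readSampleSheet(mkSheet(bad, "bad.csv"))),
               "peritumoral")

  gone <- base; gone$marker_path[2] <- "nope.png"
  expect_error(suppressMessages(readSampleSheet(mkSheet(gone, "gone.csv"))),
               "missing file")

  # an unbalanced clinical census: 33/32/13/8 images per group
  sizes <- c(33L, 32L, 13L, 8L)
  grp <- data.frame(
    tissue = rep(c("peritumoral", "peritumoral", "tumor", "tumor"), sizes),
    condition = rep(c("untreated", "treated", "untreated", "treated"), sizes)
  )
  big <- data.frame(
    image_id = sprintf("im%03d", seq_len(sum(sizes))),
    tissue = grp$tissue, condition = grp$condition,
    slice_id = "s1", marker_kind = "proliferation",
    nuclei_path = "img.png", marker_path = "img.png",
    stringsAsFactors = FALSE
  )
  expect_message(out <- readSampleSheet(mkSheet(big, "big.csv")),
                 "33")
  census <- table(out$tissue, out$condition)
  expect_equal(census["peritumoral", "untreated"], 33L, ignore_attr = TRUE)
  expect_equal(census["peritumoral", "treated"], 32L, ignore_attr = TRUE)
  expect_equal(census["tumor", "untreated"], 13L, ignore_attr = TRUE)
  expect_equal(census["tumor", "treated"], 8L, ignore_attr = TRUE)
})

test_that("channel order never affects segmentation results", {
  set.seed(21)
  sl <- generateSlide(testSpec(), seed = 5)
  img <- sl$image
  reordered <- SlideImage(img@channels[c("autofluorescence", "marker", "nuclei")],
                          pixelSize = pixelSize(img), imageId = imageId(img))
  b1 <- segmentImage(img)
  b2 <- segmentImage(reordered)
  expect_identical(b1@nuclei, b2@nuclei)
  expect_identical(b1@markerInNuclei, b2@markerInNuclei)
  expect_identical(b1@tissue, b2@tissue)
})
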