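test_that("file names split at the last underscore into sample and channel", {
  p <- parseImageName("20231212_HEK293_HAP40_c1.tiff")
  expect_equal(p$sampleName, "20231212_HEK293_HAP40")
  expect_equal(p$channelId, 1L)
  expect_equal(parseImageName("a_c2.png"), list(sampleName = "a",
                                                channelId = 2L))
  expect_equal(parseImageName("/some/dir/x_y_c10.JPG")$channelId, 10L)
})

test_that("malformed names and unsupported formats are rejected", {
  expect_error(parseImageName("image.tiff"), "naming convention")
  expect_error(parseImageName("img_c.tiff"), "naming convention")
  expect_error(parseImageName("img_c0.tiff"), ">= 1")
  expect_error(parseImageName("img_c1.bmp"), "unsupported image format")
})

test_that("a condition folder loads into a grouped, channel-ordered set", {
  d <- withr::local_tempdir()
  for (nm in c("x", "y")) {
    set.seed(match(nm, c("x", "y")))
    writeImageChannels(MultiChannelImage(nm, list(matrix(runif(64 * 48), 64),
                                                  matrix(runif(64 * 48), 64))),
                       d)
  }
  g <- loadImageGroup(d, "sample")
  expect_s4_class(g, "ImageGroup")
  expect_equal(length(g), 2L)
  expect_equal(nChannels(g), 2L)
  expect_equal(sort(vapply(groupImages(g), imageName, character(1))),
               c("x", "y"))
  expect_equal(dim(g[[1]]), c(64L, 48L))
})

test_that("TIFF round-trip reproduces intensities to within quantization", {
  d <- withr::local_tempdir()
  set.seed(3)
  orig <- matrix(runif(32 * 32), 32)
  writeImageChannels(MultiChannelImage("rt", list(orig, 1 - orig)), d)
  g <- loadImageGroup(d)
  expect_lt(max(abs(channelData(g[[1]], 1) - orig)), 1 / 65535 + 1e-9)
  expect_lt(max(abs(channelData(g[[1]], 2) - (1 - orig))), 1 / 65535 + 1e-9)
  # full-scale pixel maps to exactly 1 after bit-depth rescaling
  writeImageChannels(MultiChannelImage("fs", list(matrix(c(0, 1, 0.5, 0.25), 2))),
                     d2 <- withr::local_tempdir())
  expect_equal(max(channelData(loadImageGroup(d2)[[1]], 1)), 1)
})

test_that("grouping is invariant to file creation order", {
  set.seed(9)
  chans <- replicate(4, matrix(runif(100), 10), simplify = FALSE)
  files <- c("b_c1.tiff", "b_c2.tiff", "a_c1.tiff", "a_c2.tiff")
  mk <- function(order, d) {
    for (k in order)
      EBImage::writeImage(EBImage::Image(t(chans[[k]])),
                          file.path(d, files[k]), bits.per.sample = 16L)
    loadImageGroup(d)
  }
  g1 <- mk(1:4, withr::local_tempdir())
  g2 <- mk(c(3, 1, 4, 2), withr::local_tempdir())
  expect_equal(vapply(groupImages(g1), imageName, character(1)),
               vapply(groupImages(g2), imageName, character(1)))
  expect_equal(channelData(g1[[1]], 1), channelData(g2[[1]], 1))
})

test_that("gapped channels, mixed counts and mismatched dims are errors", {
  d <- withr::local_tempdir()
  m <- matrix(runif(64), 8)
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d, "x_c1.tiff"))
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d, "x_c3.tiff"))
  expect_error(loadImageGroup(d), "non-contiguous")

  d2 <- withr::local_tempdir()
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d2, "x_c1.tiff"))
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d2, "x_c2.tiff"))
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d2, "y_c1.tiff"))
  expect_error(loadImageGroup(d2), "different channel counts")

  d3 <- withr::local_tempdir()
  EBImage::writeImage(EBImage::Image(t(m)), file.path(d3, "x_c1.tiff"))
  EBImage::writeImage(EBImage::Image(t(matrix(runif(36), 6))),
                      file.path(d3, "x_c2.tiff"))
  expect_error(loadImageGroup(d3), "mismatched dimensions")

  expect_error(loadImageGroup(withr::local_tempdir()), "no image files")
})

test_that("RGB planes collapse to luminance with a warning", {
  d <- withr::local_tempdir()
  arr <- array(runif(8 * 8 * 3), c(8, 8, 3))
  png::writePNG(arr, file.path(d, "rgb_c1.png"))
  expect_warning(g <- loadImageGroup(d), "luminance")
  expect_equal(dim(g[[1]]), c(8L, 8L))
  lum <- t(0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3])
  expect_equal(channelData(g[[1]], 1), t(lum), tolerance = 1 / 255)
})
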