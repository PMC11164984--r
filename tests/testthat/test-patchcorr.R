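test_that("correlate handles identities, reversals and undefined inputs", {
  x <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  for (m in c("pearson", "spearman", "kendall"))
    expect_equal(correlate(x, x, m), 1)
  expect_equal(correlate(x, -x + 1, "pearson"), -1)
  expect_equal(correlate(x, -x + 1, "spearman"), -1)
  expect_true(is.na(correlate(rep(0.5, 5), x)))
  expect_true(is.na(correlate(x, rep(0.2, 5))))
  expect_true(is.na(correlate(0.3, 0.4)))
  expect_error(correlate(x, x[-1]), "equal length")
})

test_that("rank correlations match brute-force oracles on tied data", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    x <- round(runif(n), 1)   # rounding forces ties
    y <- round(runif(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(correlate(x, y, "spearman"), bruteSpearman(x, y),
                 tolerance = 1e-12)
    expect_equal(correlate(x, y, "kendall"), bruteKendall(x, y),
                 tolerance = 1e-12)
  }
  # spec'd identity: Spearman is Pearson on average ranks, exactly
  x <- c(1, 2, 2, 3, 5, 5); y <- c(2, 1, 4, 4, 6, 5)
  expect_identical(correlate(x, y, "spearman"),
                   correlate(rank(x), rank(y), "pearson"))
})

test_that("patch grids tile by floor division and drop the remainder", {
  g <- patchGrid(c(64, 64), 16)
  expect_equal(nrow(g), 256)
  expect_true(all(g$rowEnd - g$rowStart == 3))
  expect_equal(attr(g, "droppedRows"), 0L)

  g1 <- patchGrid(c(10, 10), 1)
  expect_equal(nrow(g1), 1)
  expect_equal(c(g1$rowStart, g1$rowEnd, g1$colStart, g1$colEnd),
               c(1, 10, 1, 10))

  g3 <- patchGrid(c(10, 10), 3)
  expect_equal(nrow(g3), 9)
  expect_true(all(g3$rowEnd - g3$rowStart == 2))
  expect_equal(attr(g3, "droppedRows"), 1L)
  expect_equal(attr(g3, "droppedCols"), 1L)
  expect_equal(max(g3$rowEnd), 9)

  expect_error(patchGrid(c(10, 10), 11), "exceeds")
})

test_that("every patch correlation equals the direct masked computation", {
  im <- makeTestImage(41, H = 48, W = 48, rho = 0.6)
  set.seed(42)
  mask <- matrix(runif(48 * 48) < 0.6, 48)
  for (m in c("pearson", "spearman")) {
    pc <- patchCorrelations(im, 1, 2, mask, nPatchesSide = 6, method = m)
    g <- patchGrid(dim(im), 6)
    for (p in seq_len(nrow(g))) {
      expected <- bruteMaskedCorr(channelData(im, 1), channelData(im, 2),
                                  mask, g$rowStart[p]:g$rowEnd[p],
                                  g$colStart[p]:g$colEnd[p], m)
      expect_equal(corrValues(pc)[g$row[p] + 1, g$col[p] + 1], expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("the minimum-pixel rule invalidates sparse patches", {
  im <- makeTestImage(43, H = 8, W = 8)
  mask <- matrix(FALSE, 8, 8)
  mask[which(matrix(TRUE, 8, 8))[1:14]] <- TRUE  # exactly 14 valid pixels
  pc <- patchCorrelations(im, 1, 2, mask, 1, minValid = 15)
  expect_true(is.na(corrValues(pc)[1, 1]))
  mask[15] <- TRUE                               # the 15th turns it valid
  pc <- patchCorrelations(im, 1, 2, mask, 1, minValid = 15)
  expect_false(is.na(corrValues(pc)[1, 1]))
  # identical channel values across valid pixels give exactly 1
  a <- matrix(runif(64), 8)
  im2 <- MultiChannelImage("same", list(a, a))
  pc2 <- patchCorrelations(im2, 1, 2, matrix(TRUE, 8, 8), 1)
  expect_equal(corrValues(pc2)[1, 1], 1)
})

test_that("patch validity is monotone in minValid and in the mask", {
  im <- makeTestImage(44, H = 40, W = 40)
  set.seed(45)
  mask <- matrix(runif(1600) < 0.5, 40)
  counts <- vapply(c(5, 10, 15, 20, 25), function(mv)
    sum(validPatches(patchCorrelations(im, 1, 2, mask, 5, minValid = mv))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  shrunk <- mask & (matrix(runif(1600), 40) < 0.8)
  v1 <- validPatches(patchCorrelations(im, 1, 2, mask, 5))
  v2 <- validPatches(patchCorrelations(im, 1, 2, shrunk, 5))
  expect_true(all(v1 | !v2))  # shrinking never turns an invalid patch valid
})

test_that("adaptive search keeps dense grids and halves sparse ones", {
  im <- makeTestImage(46, H = 64, W = 64)
  dense <- matrix(TRUE, 64, 64)
  pc <- adaptivePatchSearch(im, 1, 2, dense, requestedN = 16)
  expect_equal(nPatchesSide(pc), 16L)

  # one small grid-aligned cell: 32x32 patches (2x2 px) can never reach 15
  # valid pixels, 16x16 patches (4x4 px) give 9 fully covered patches
  sparse <- matrix(FALSE, 64, 64)
  sparse[17:28, 17:28] <- TRUE
  n32 <- sum(validPatches(patchCorrelations(im, 1, 2, sparse, 32)))
  n16 <- sum(validPatches(patchCorrelations(im, 1, 2, sparse, 16)))
  expect_equal(n32, 0)
  expect_equal(n16, 9)
  expect_warning(pc2 <- adaptivePatchSearch(im, 1, 2, sparse, 32),
                 "ADAPTIVE")
  expect_equal(nPatchesSide(pc2), 16L)

  empty <- matrix(FALSE, 64, 64)
  expect_warning(out <- adaptivePatchSearch(im, 1, 2, empty, 16), "EXCLUDED")
  expect_null(out)
})

test_that("local correlation maps match per-window direct computation", {
  im <- makeTestImage(47, H = 24, W = 20, rho = 0.5)
  set.seed(48)
  mask <- matrix(runif(24 * 20) < 0.7, 24)
  a <- channelData(im, 1); b <- channelData(im, 2)
  lm <- localCorrelationMap(im, 1, 2, mask, windowSide = 7,
                            method = "pearson", minValid = 15)
  vals <- corrValues(lm)
  for (i in c(4, 10, 17, 21)) for (j in c(4, 9, 14, 17)) {
    expected <- bruteMaskedCorr(a, b, mask, (i - 3):(i + 3), (j - 3):(j + 3),
                                "pearson")
    expect_equal(vals[i, j], expected, tolerance = 1e-8)
  }
  # outside the interior the map is undefined
  expect_true(all(is.na(vals[1:3, ])))
  # identical channels give 1 wherever defined
  im2 <- MultiChannelImage("same", list(a, a))
  lm2 <- localCorrelationMap(im2, 1, 2, mask, 7)
  expect_true(all(abs(corrValues(lm2)[is.finite(corrValues(lm2))] - 1) < 1e-8))
  # a window fully in background is missing
  holed <- mask; holed[6:16, 6:16] <- FALSE
  lm3 <- localCorrelationMap(im, 1, 2, holed, 7)
  expect_true(is.na(corrValues(lm3)[11, 11]))
  expect_error(localCorrelationMap(im, 1, 2, mask, 30), "larger than")
})

test_that("rank-method local maps agree with the direct oracle", {
  im <- makeTestImage(49, H = 16, W = 16, rho = 0.4)
  mask <- matrix(TRUE, 16, 16)
  lm <- localCorrelationMap(im, 1, 2, mask, 5, method = "spearman",
                            minValid = 10)
  a <- channelData(im, 1); b <- channelData(im, 2)
  for (i in c(5, 9)) for (j in c(5, 12)) {
    expect_equal(corrValues(lm)[i, j],
                 bruteMaskedCorr(a, b, mask, (i - 2):(i + 2), (j - 2):(j + 2),
                                 "spearman", 10),
                 tolerance = 1e-12)
  }
})
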