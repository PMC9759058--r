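test_that("frame order follows the numeric index, not lexicographic order", {
  d <- withr::local_tempdir()
  png::writePNG(matrix(26 / 255, 8, 8), file.path(d, "f_2.png"))
  png::writePNG(matrix(230 / 255, 8, 8), file.path(d, "f_10.png"))
  cs <- loadChannelSeries(d, "interstitial")
  expect_equal(nFrames(cs), 2L)
  expect_equal(getFrame(cs, 1)[1, 1], 26)   # f_2 first
  expect_equal(getFrame(cs, 2)[1, 1], 230)  # then f_10
})

test_that("load errors: empty directory, mixed geometry, duplicate index", {
  d <- withr::local_tempdir()
  expect_error(loadChannelSeries(d, "interstitial"), "no frames found")
  png::writePNG(matrix(0, 8, 8), file.path(d, "a_000.png"))
  png::writePNG(matrix(0, 4, 4), file.path(d, "a_001.png"))
  expect_error(loadChannelSeries(d, "interstitial"),
               "inconsistent frame geometry")
  d2 <- withr::local_tempdir()
  png::writePNG(matrix(0, 8, 8), file.path(d2, "a_1.png"))
  png::writePNG(matrix(0, 8, 8), file.path(d2, "b_001.png"))
  expect_error(loadChannelSeries(d2, "interstitial"), "ambiguous frame order")
})

test_that("write/load round-trips are identity at 8-bit precision", {
  set.seed(11)
  fr <- lapply(1:5, function(i) matrix(sample(0:255, 64, TRUE), 8, 8))
  cs <- ChannelSeries(fr, "neutrophil")
  for (fmt in c("png", "tiff")) {
    d <- withr::local_tempdir()
    writeChannelSeries(cs, d, format = fmt)
    back <- loadChannelSeries(d, "neutrophil")
    expect_equal(frames(back), frames(cs), ignore_attr = TRUE)
  }
})

test_that("channel compositing assigns blue to interstitium, red to neutrophils, zero green", {
  i <- matrix(0, 6, 6); i[4, 4] <- 200
  n <- matrix(0, 6, 6); n[1, 1] <- 255
  comp <- combineChannels(ChannelSeries(i, "interstitial"),
                          ChannelSeries(n, "neutrophil"))[[1]]
  expect_equal(comp[4, 4, ], c(0, 0, 200))   # dextran-bright pixel is blue
  expect_equal(comp[1, 1, ], c(255, 0, 0))   # labeled neutrophil is red
  expect_true(all(comp[, , 2] == 0))
  # lossless: the planes reconstruct both inputs exactly
  expect_equal(comp[, , 3], i)
  expect_equal(comp[, , 1], n)
  # all-zero channels give an all-black composite
  z <- ChannelSeries(matrix(0, 6, 6), "interstitial")
  z2 <- ChannelSeries(matrix(0, 6, 6), "neutrophil")
  expect_true(all(combineChannels(z, z2)[[1]] == 0))
})

test_that("compositing rejects misaligned series", {
  a <- ChannelSeries(matrix(0, 6, 6), "interstitial")
  b <- ChannelSeries(list(matrix(0, 6, 6), matrix(0, 6, 6)), "neutrophil")
  expect_error(combineChannels(a, b), "not aligned")
  c2 <- ChannelSeries(matrix(0, 4, 6), "neutrophil")
  expect_error(combineChannels(a, c2), "not aligned")
})

test_that("feature tables round-trip through CSV and refuse empty input", {
  stats <- do.call(rbind, lapply(0:4, function(i)
    computeFrameStats(list(makeContour(1000 + i, 10, 10)), list(), NULL,
                      c(100, 100), frameIndex = i)))
  d <- withr::local_tempdir()
  p <- file.path(d, "stats.csv")
  writeFeatureTable(stats, p)
  expect_true(file.exists(file.path(d, "stats.json")))
  back <- readFeatureTable(p)
  expect_equal(nrow(back), 5L)
  expect_equal(back$alveolar_area_pct, stats$alveolar_area_pct,
               tolerance = 1e-6)
  expect_error(writeFeatureTable(stats[0, ], file.path(d, "e.csv")), "empty")
})
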