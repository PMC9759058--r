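test_that("the generator is bit-identical under a fixed seed and leaves the RNG alone", {
  cfg <- smallSceneConfig()
  set.seed(999)
  before <- .Random.seed
  a <- generateScene(cfg)
  expect_identical(.Random.seed, before)  # global RNG untouched
  b <- generateScene(cfg)
  expect_identical(frames(a$interstitial), frames(b$interstitial))
  expect_identical(frames(a$neutrophil), frames(b$neutrophil))
  expect_identical(a$truth, b$truth)
  # a different seed changes the scene
  c2 <- generateScene(smallSceneConfig(seed = 8L))
  expect_false(identical(frames(a$interstitial), frames(c2$interstitial)))
})

test_that("a still, noiseless single-alveolus scene rasterizes to the analytic disk", {
  cfg <- SyntheticConfig(height = 128, width = 128, nFrames = 4,
                         nAlveoli = 1, alveolusRadiusRange = c(20, 20),
                         breathingAmplitude = 0, nNeutrophils = 0,
                         nTransients = 0, noiseSigma = 0)
  sc <- generateScene(cfg)
  f1 <- getFrame(sc$interstitial, 1)
  # every frame identical when the breathing amplitude is zero
  for (i in 2:4) expect_identical(getFrame(sc$interstitial, i), f1)
  dark <- sum(f1 < 100)
  expect_lt(abs(dark - pi * 20^2) / (pi * 20^2), 0.02)
})

test_that("ground-truth areas follow the breathing signal and match rasterization", {
  cfg <- smallSceneConfig(breathingAmplitude = 0.25, breathingPeriod = 16,
                          nFrames = 17)
  sc <- generateScene(cfg)
  alv <- sc$truth[sc$truth$role == "interstitial", ]
  a0 <- alv$area[alv$frame == 0]
  a4 <- alv$area[alv$frame == 4]   # sine peak: s = 1.25
  expect_equal(a4, 1.25^2 * a0)
  # analytic area vs rasterized pixel count, radii >= 8 px
  cfg2 <- SyntheticConfig(height = 256, width = 256, nFrames = 2,
                          nAlveoli = 4, alveolusRadiusRange = c(8, 25),
                          breathingAmplitude = 0, nNeutrophils = 0,
                          nTransients = 0, noiseSigma = 0, seed = 5L)
  sc2 <- generateScene(cfg2)
  m <- getFrame(sc2$interstitial, 1) < 100
  ct <- extractContours(matrix(as.integer(m), nrow(m), ncol(m)),
                        "interstitial")
  tr <- sc2$truth[sc2$truth$frame == 0, ]
  expect_length(ct, 4L)
  for (j in seq_len(nrow(tr))) {
    dists <- vapply(ct, function(x)
      sqrt(sum((x$centroid - c(tr$x[j], tr$y[j]))^2)), numeric(1))
    expect_lt(abs(ct[[which.min(dists)]]$area - tr$area[j]) / tr$area[j], 0.03)
  }
})

test_that("transients appear in exactly one frame, persistent features in every frame", {
  cfg <- smallSceneConfig(nTransients = 3)
  sc <- generateScene(cfg)
  tab <- table(sc$truth$feature_id)
  persistentIds <- unique(sc$truth$feature_id[sc$truth$persistent])
  transientIds <- unique(sc$truth$feature_id[!sc$truth$persistent])
  expect_length(transientIds, 3L)
  expect_true(all(tab[transientIds] == 1L))
  expect_true(all(tab[persistentIds] == cfg@nFrames))
})

test_that("infeasible placement is reported rather than looping forever", {
  cfg <- SyntheticConfig(height = 64, width = 64, nFrames = 2, nAlveoli = 30,
                         alveolusRadiusRange = c(14, 16), nNeutrophils = 0,
                         nTransients = 0, noiseSigma = 0)
  expect_error(generateScene(cfg), "cannot place features")
})

test_that("a written scene round-trips through the standard I/O path", {
  sc <- generateScene(smallSceneConfig(nFrames = 4))
  d <- withr::local_tempdir()
  writeScene(sc, d)
  inter <- loadChannelSeries(file.path(d, "interstitial"), "interstitial")
  neut <- loadChannelSeries(file.path(d, "neutrophil"), "neutrophil")
  expect_equal(frames(inter), frames(sc$interstitial), ignore_attr = TRUE)
  expect_equal(frames(neut), frames(sc$neutrophil), ignore_attr = TRUE)
  truth <- read.csv(file.path(d, "ground_truth.csv"))
  expect_equal(nrow(truth), nrow(sc$truth))
})
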