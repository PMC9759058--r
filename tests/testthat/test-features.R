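test_that("frame statistics follow the area-percentage arithmetic", {
  one <- computeFrameStats(list(makeContour(1000, 10, 10)), list(), NULL,
                           c(100, 100))
  expect_equal(one$alveolar_area_pct, 10)
  expect_equal(one$airspace_per_alveolus_pct, 10)
  four <- computeFrameStats(lapply(1:4, function(i) makeContour(500, i, i)),
                            list(), NULL, c(100, 100))
  expect_equal(four$alveolar_area_pct, 20)
  expect_equal(four$airspace_per_alveolus_pct, 5)
  expect_equal(four$alveoli_count, 4L)
  # empty frame: all zeros, and zero count implies zero percentages
  zero <- computeFrameStats(list(), list(), matrix(0L, 10, 10), c(10, 10))
  expect_true(all(zero[, -1] == 0))
  # interstitial mask fraction and neutrophil area
  im <- matrix(0L, 10, 10); im[1:5, ] <- 1L
  st <- computeFrameStats(list(), list(makeContour(25, 3, 3, "neutrophil")),
                          im, c(10, 10))
  expect_equal(st$interstitial_area_pct, 50)
  expect_equal(st$neutrophil_area_pct, 25)
  expect_error(computeFrameStats(list(), list(), NULL, c(0, 10)), "dimensions")
})

test_that("frame statistics are linear in contour areas", {
  cts <- lapply(c(300, 700, 150), function(a) makeContour(a, 5, 5))
  s1 <- computeFrameStats(cts, list(), NULL, c(200, 200))
  cts2 <- lapply(cts, function(ct) { ct$area <- 2 * ct$area; ct })
  s2 <- computeFrameStats(cts2, list(), NULL, c(200, 200))
  expect_equal(s2$alveolar_area_pct, 2 * s1$alveolar_area_pct)
})

test_that("cycle detection recovers the sinusoid's troughs, spans and extremes", {
  s <- sineStats(64, 16)
  cyc <- detectCycles(s)
  expect_equal(nrow(cyc), 3L)
  expect_equal(cyc$start_frame, c(12L, 28L, 44L))  # analytic minima of the sine
  expect_equal(cyc$end_frame, c(28L, 44L, 60L))
  expect_equal(cyc$end_frame - cyc$start_frame, rep(16L, 3))
  # cycles tile the covered range
  expect_equal(cyc$end_frame[-3], cyc$start_frame[-1])
  # extremes from the unsmoothed signal within one sample of the analytic 5/15
  expect_true(all(abs(cyc$min_alveolar_pct - 5) < 5 * (1 - cos(pi / 8)) + 1e-9))
  expect_true(all(abs(cyc$max_alveolar_pct - 15) < 5 * (1 - cos(pi / 8)) + 1e-9))
  expect_true(all(cyc$min_alveolar_pct <= cyc$max_alveolar_pct))
})

test_that("cycle detection fails cleanly on constant or too-short series", {
  const <- sineStats(40, 16, amp = 0)
  expect_error(detectCycles(const), "no complete respiratory cycle")
  expect_error(detectCycles(sineStats(6, 16)), "too short")
})

test_that("detected cycle count and length track the configured period", {
  for (period in c(8, 12, 20)) {
    s <- sineStats(4 * period + 2, period)
    cyc <- detectCycles(s, minCycleLen = max(4L, period %/% 3))
    expect_true(all(abs((cyc$end_frame - cyc$start_frame) - period) <= 1))
    expect_gte(nrow(cyc), 3L)
  }
})

test_that("cycle overlay re-indexes traces to a shared phase axis", {
  s <- sineStats(64, 16)
  cyc <- detectCycles(s)
  ov <- cycleOverlay(s, cyc)
  traces <- split(ov$alveolar_area_pct, ov$cycle_index)
  expect_length(traces, 3L)
  # a periodic signal yields pairwise-equal traces with aligned peaks
  expect_equal(traces[[1]], traces[[2]], tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(traces[[2]], traces[[3]], tolerance = 1e-12, ignore_attr = TRUE)
  phases <- split(ov$phase, ov$cycle_index)
  expect_equal(unique(vapply(seq_along(traces), function(i)
    phases[[i]][which.max(traces[[i]])], numeric(1))), 8)
})

test_that("experiment summary reports the radar axes and normalizes across experiments", {
  s <- sineStats(64, 16)
  cyc <- detectCycles(s)
  sm <- summarizeExperiment(s, cyc)
  expect_equal(unname(sm["mean_neutrophil_count"]), 3)
  expect_equal(unname(sm["mean_cycle_length"]), 16)
  # peak-to-trough amplitude of the amp-5 sinusoid is close to 10
  expect_equal(unname(sm["mean_cycle_amplitude"]), 10, tolerance = 0.02)
  # no cycles: amplitude and length axes absent
  sm0 <- summarizeExperiment(s, NULL)
  expect_true(is.na(sm0["mean_cycle_amplitude"]))
  expect_true(is.na(sm0["mean_cycle_length"]))
  # min-max normalization maps two experiments to 0 and 1
  a <- sm; a["mean_neutrophil_count"] <- 2
  b <- sm; b["mean_neutrophil_count"] <- 6
  nm <- normalizeSummaries(list(a, b))
  expect_equal(unname(nm[, "mean_neutrophil_count"]), c(0, 1))
  expect_true(all(nm >= 0 & nm <= 1, na.rm = TRUE))
})
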