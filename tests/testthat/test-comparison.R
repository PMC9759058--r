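test_that("offset shifting drops frames and re-bases indices", {
  s <- sineStats(10, 4)
  expect_equal(applyOffset(s, 0), s)
  sh <- applyOffset(s, 3)
  expect_equal(nrow(sh), 7L)
  expect_equal(sh$frame_index, 0:6)
  expect_equal(sh$alveolar_area_pct, s$alveolar_area_pct[4:10])
  neg <- applyOffset(s, -2)
  expect_equal(nrow(neg), 8L)
  expect_equal(neg$alveolar_area_pct, s$alveolar_area_pct[1:8])
  expect_error(applyOffset(s, 10), "exceeds")
  expect_error(applyOffset(s, -12), "exceeds")
})

test_that("slope chart takes first- and last-cycle means", {
  s <- sineStats(64, 16)
  cyc <- detectCycles(s)
  # constant features give equal endpoints
  expect_equal(unname(slopeChart(s, cyc, "neutrophil_count")), c(3, 3))
  # a linear ramp: endpoint means are the analytic means of each cycle span
  s$interstitial_area_pct <- s$frame_index
  sp <- slopeChart(s, cyc, "interstitial_area_pct")
  expect_equal(unname(sp), c(mean(12:27), mean(44:59)))
  # a single cycle makes both endpoints the same cycle
  one <- cyc[1, , drop = FALSE]
  sp1 <- slopeChart(s, one, "interstitial_area_pct")
  expect_equal(sp1[["start_value"]], sp1[["end_value"]])
  expect_error(slopeChart(s, cyc, "elastance"), "unknown feature")
  expect_error(slopeChart(s, cyc[0, ], "neutrophil_count"), "cycle")
})

test_that("distribution summary uses interpolated quantiles and attaches raw values", {
  s <- sineStats(5, 16)
  s$neutrophil_area_pct <- c(1, 2, 3, 4, 5)
  d <- distributionSummary(s, "neutrophil_area_pct")
  expect_equal(d[["median"]], 3)
  expect_equal(d[["mean"]], 3)
  s$neutrophil_area_pct <- c(0, 0, 0, 10, 0)[1:5]
  s2 <- s[1:4, ]
  s2$neutrophil_area_pct <- c(0, 0, 0, 10)
  d2 <- distributionSummary(s2, "neutrophil_area_pct")
  expect_equal(d2[["mean"]], 2.5)
  expect_equal(d2[["q75"]], 2.5)  # linear interpolation between 0 and 10
  expect_equal(unname(d2[c("min", "q25", "median", "q75", "max")]),
               sort(unname(d2[c("min", "q25", "median", "q75", "max")])))
  s3 <- s; s3$neutrophil_area_pct <- rep(4, 5)
  expect_true(all(distributionSummary(s3, "neutrophil_area_pct") == 4))
  expect_equal(attr(d2, "values"), c(0, 0, 0, 10))
  expect_error(distributionSummary(s[0, ], "neutrophil_area_pct"), "empty")
})

test_that("per-cycle differences are symmetric, aligned and zero for identical input", {
  a <- sineStats(64, 16)
  cycA <- detectCycles(a)
  expect_equal(cycleDifferenceChart(a, cycA, a, cycA, "alveolar_area_pct"),
               rep(0, 3))
  b <- a
  b$neutrophil_count <- 5L
  cycB <- detectCycles(b)
  d <- cycleDifferenceChart(a, cycA, b, cycB, "neutrophil_count")
  expect_equal(d, rep(2, 3))
  expect_equal(d, cycleDifferenceChart(b, cycB, a, cycA, "neutrophil_count"))
  # min-rule on unequal cycle counts
  shortB <- sineStats(34, 16)
  cycS <- detectCycles(shortB)
  expect_length(cycleDifferenceChart(a, cycA, shortB, cycS, "alveolar_area_pct"),
                min(nrow(cycA), nrow(cycS)))
})

test_that("self-comparison at zero offset is the identity case", {
  s <- sineStats(64, 16)
  cmp <- compareExperiments(s, s, offsetFrames = 0L)
  for (f in names(cmp$cycle_differences))
    expect_true(all(cmp$cycle_differences[[f]] == 0))
  for (f in names(cmp$slope_pairs))
    expect_equal(cmp$slope_pairs[[f]]$A, cmp$slope_pairs[[f]]$B)
  # zero offset leaves slope and distribution results invariant
  expect_equal(cmp$slope_pairs$alveolar_area_pct$A,
               slopeChart(s, detectCycles(s), "alveolar_area_pct"))
  # serialization round-trips the document structure
  p <- file.path(withr::local_tempdir(), "cmp.json")
  writeComparisonJSON(cmp, p)
  doc <- jsonlite::read_json(p)
  expect_equal(doc$offset_frames, 0L)
  expect_length(doc$cycle_differences$alveolar_area_pct, 3L)
})

test_that("offset suggestion recovers a known phase shift", {
  a <- sineStats(64, 16)
  shifted <- sineStats(70, 16)[7:70, ]     # B leads A by 6 frames
  shifted$frame_index <- 0:63
  expect_equal(suggestOffset(a, applyOffset(sineStats(64, 16), 0)), 0)
  b <- sineStats(64, 16)
  b$alveolar_area_pct <- 10 + 5 * sin(2 * pi * ((0:63) + 6) / 16)
  expect_equal(suggestOffset(b, a, maxLag = 8), 6)
})
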