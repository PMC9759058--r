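test_that("feature matching combines centroid proximity with the area rule", {
  pol <- defaultTrackPolicy("interstitial")
  pol@areaToleranceRel <- 0.3
  pol@centroidRadius <- 15
  # 200 <= 0.3 * 1200 and 3 px <= 15 px
  expect_true(featuresMatch(makeContour(1000, 10, 10), makeContour(1200, 13, 10), pol))
  # identical contours always match
  expect_true(featuresMatch(makeContour(500, 4, 4), makeContour(500, 4, 4), pol))
  # relative rule fails when the area gap exceeds the allowance
  # (500 > 0.3 * max(1000, 1500) = 450)
  expect_false(featuresMatch(makeContour(1000, 10, 10), makeContour(1500, 10, 10), pol))
  # neutrophils: absolute tolerance and distance gating
  pn <- defaultTrackPolicy("neutrophil")
  a <- makeContour(100, 0, 0, role = "neutrophil")
  expect_false(featuresMatch(a, makeContour(100, 50, 0, role = "neutrophil"), pn))
  expect_true(featuresMatch(a, makeContour(140, 5, 0, role = "neutrophil"), pn))
  expect_false(featuresMatch(a, makeContour(170, 5, 0, role = "neutrophil"), pn))
  expect_error(featuresMatch(a, makeContour(100, 0, 0, role = "interstitial"), pn),
               "roles")
})

test_that("temporal filter keeps features with a matching neighbor and drops one-frame blobs", {
  pol <- defaultTrackPolicy("neutrophil")
  stable <- function(f) makeContour(100, 20, 20, "neutrophil", f)
  det <- lapply(0:9, function(f) list(stable(f)))
  det[[6]] <- list(stable(5), makeContour(100, 70, 70, "neutrophil", 5))
  out <- filterByTemporalConsistency(det, pol)
  # the persistent blob survives everywhere, including first and last frames
  expect_equal(vapply(out$kept, length, integer(1)), rep(1L, 10))
  # the frame-5 transient was rejected with a reason
  expect_equal(nrow(out$rejections), 1L)
  expect_equal(out$rejections$frame_index, 5L)
  expect_match(out$rejections$reason, "neighboring frame")
})

test_that("one matching neighbor suffices: the two-condition rule is existential", {
  pol <- defaultTrackPolicy("neutrophil")
  # frame 2's blob matches frame 1's but not frame 3's
  det <- list(list(makeContour(100, 20, 20, "neutrophil", 0)),
              list(makeContour(110, 22, 20, "neutrophil", 1)),
              list(makeContour(400, 22, 20, "neutrophil", 2)))
  out <- filterByTemporalConsistency(det, pol)
  expect_length(out$kept[[2]], 1L)
  # frame 1 matches frame 2; frame 3 matches nothing within tolerance
  expect_length(out$kept[[1]], 1L)
  expect_length(out$kept[[3]], 0L)
})

test_that("kept set equals the neighbor-existence predicate on random detections", {
  pol <- defaultTrackPolicy("neutrophil")
  set.seed(23)
  for (rep in 1:10) {
    det <- lapply(0:7, function(f) {
      k <- rpois(1, 3)
      lapply(seq_len(k), function(i)
        makeContour(runif(1, 40, 400), runif(1, 0, 100), runif(1, 0, 100),
                    "neutrophil", f))
    })
    out <- filterByTemporalConsistency(det, pol)
    for (t in seq_along(det)) {
      expected <- Filter(function(ct) {
        nb <- c(if (t > 1) det[[t - 1]], if (t < length(det)) det[[t + 1]])
        any(vapply(nb, featuresMatch, logical(1), a = ct, policy = pol))
      }, det[[t]])
      expect_identical(out$kept[[t]], expected)
    }
  }
})

test_that("the filter needs at least two frames", {
  expect_error(
    filterByTemporalConsistency(list(list()), defaultTrackPolicy("neutrophil")),
    ">=2 frames")
})

test_that("track linking assigns stable IDs to persistent features", {
  pol <- defaultTrackPolicy("neutrophil")
  det <- lapply(0:5, function(f)
    list(makeContour(100, 20 + f, 20, "neutrophil", f),
         makeContour(80, 70, 70 - f, "neutrophil", f)))
  ids <- linkTracks(det, pol)
  expect_equal(vapply(ids, `[`, integer(1), 1L), rep(1L, 6))
  expect_equal(vapply(ids, `[`, integer(1), 2L), rep(2L, 6))
  # a feature appearing mid-sequence opens a new track
  det[[4]] <- c(det[[4]], list(makeContour(60, 45, 45, "neutrophil", 3)))
  ids2 <- linkTracks(det, pol)
  expect_equal(ids2[[4]][3], 3L)
})
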