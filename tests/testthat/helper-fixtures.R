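# shared fixture builders and independent oracles

# a minimal contour record
makeContour <- function(area, cx, cy, role = "interstitial", frame = 0L) {
  list(polygon = cbind(x = c(cx - 1, cx + 1, cx), y = c(cy - 1, cy - 1, cy + 1)),
       area = area, centroid = c(x = cx, y = cy), role = role,
       frame_index = as.integer(frame))
}

# brute-force 8-connected component labeling: plain BFS over the pixel set,
# independent of the package implementation
oracleComponents <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nl <- 0L
  for (c in seq_len(ncol(mask))) for (r in seq_len(nrow(mask))) {
    if (mask[r, c] == 1L && lab[r, c] == 0L) {
      nl <- nl + 1L
      queue <- list(c(r, c)); lab[r, c] <- nl
      while (length(queue)) {
        p <- queue[[1L]]; queue <- queue[-1L]
        for (dy in -1:1) for (dx in -1:1) {
          qr <- p[1L] + dy; qc <- p[2L] + dx
          if (qr >= 1L && qr <= nrow(mask) && qc >= 1L && qc <= ncol(mask) &&
              mask[qr, qc] == 1L && lab[qr, qc] == 0L) {
            lab[qr, qc] <- nl
            queue[[length(queue) + 1L]] <- c(qr, qc)
          }
        }
      }
    }
  }
  list(n = nl, areas = if (nl > 0L) as.integer(table(lab[lab > 0L])) else integer())
}

# frame-statistics series following a pure sinusoid
sineStats <- function(n = 64L, period = 16, base = 10, amp = 5) {
  t <- seq_len(n) - 1L
  data.frame(frame_index = t,
             alveolar_area_pct = base + amp * sin(2 * pi * t / period),
             alveoli_count = 6L, airspace_per_alveolus_pct = 2,
             neutrophil_count = 3L, neutrophil_area_pct = 1,
             interstitial_area_pct = 80)
}

# small fast synthetic configuration for unit tests; ... overrides defaults
smallSceneConfig <- function(...) {
  args <- list(height = 96, width = 96, nFrames = 24, breathingPeriod = 8,
               nAlveoli = 2, alveolusRadiusRange = c(10, 14),
               nNeutrophils = 2, neutrophilRadiusRange = c(4, 6),
               nTransients = 2, noiseSigma = 0, seed = 7L)
  user <- list(...)
  args[names(user)] <- user
  do.call(SyntheticConfig, args)
}
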