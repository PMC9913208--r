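# Extremum extraction, stride segmentation and the asymmetry metrics.

test_that("extrema of a pure double-harmonic match the closed form", {
  rate <- 200; f <- 1.4
  t <- seq(0, 5, by = 1 / rate)
  v <- vd_signal(sin(4 * pi * f * t), rate, "head", "mc")
  ex <- extract_extrema(v, edge_s = 0)
  # peaks of sin(4 pi f t) at t = 1/(8f) + k/(2f)
  expected_peaks <- seq(1 / (8 * f), 5, by = 1 / (2 * f))
  got_peaks <- ex$t[ex$kind == "peak"]
  expect_equal(length(got_peaks),
               sum(expected_peaks > 0 & expected_peaks < 5))
  expect_lt(max(abs(got_peaks - expected_peaks[seq_along(got_peaks)])),
            1 / rate)
  expect_true(all(ex$kind[seq(1, nrow(ex), by = 2)] != ex$kind[2]))
})

test_that("plateaus yield one extremum at the plateau midpoint", {
  y <- c(0, 1, 2, 2, 1, 0, -1, -2, -1, 0, 2, 0, -2, 0, 1, 0)
  v <- vd_signal(y, 10, "head", "mc")
  ex <- extract_extrema(v, edge_s = 0)
  p1 <- ex[ex$kind == "peak", ][1, ]
  expect_equal(p1$t, (0.2 + 0.3) / 2)  # two equal samples at t = 0.2, 0.3
  expect_equal(p1$y, 2)
})

test_that("same-kind runs reduce to the most extreme member", {
  # double bump without a real valley between (monotone plateau breaks)
  y <- c(0, 3, 1, 2, 0, -3, 0)
  v <- vd_signal(y, 1, "head", "mc")
  ex <- extract_extrema(v, edge_s = 0)
  expect_equal(nrow(ex[ex$kind == "peak", ]), 2)
  expect_equal(max(ex$y), 3)
  # alternation strictly enforced
  expect_true(all(ex$kind[-1] != ex$kind[-nrow(ex)]))
})

test_that("robust extraction equals standard extraction for symmetric gaits", {
  sim <- generate_trial(trot_config(n_strides = 12, noise_sd = c(mc = 0, sc = 0),
                                    stride_jitter = 0, drift = 0,
                                    glitch_frac = 0, seed = 5))
  v <- sim$recording$signals[["mc.head"]]
  fi <- stride_frequency(sim$recording, "sc")
  bp <- bandpass_vds(v, fi$f_stride)
  std <- extract_extrema(bp)
  rob <- robust_extrema(bp, fi$f_stride)
  shared <- min(nrow(std), nrow(rob))
  expect_gt(shared, 40)
  expect_lt(max(abs(std$t[1:shared] - rob$t[1:shared])), 1 / v$rate + 1e-9)
})

test_that("robust extraction recovers both valleys in severe lameness", {
  rate <- 200; f <- 1.4
  t <- seq(0, 10, by = 1 / rate)
  # extremum cancellation in a two-harmonic sum requires the first
  # harmonic to exceed twice the second (root of the derivative leaving
  # the unit circle); 50 > 2 * 20 puts us in the one-valley regime
  y <- 20 * sin(4 * pi * f * t) + 50 * sin(2 * pi * f * t)
  v <- vd_signal(y, rate, "head", "mc")
  attr(v, "edge_s") <- 1.5 / f

  # dense-grid oracle: the raw signal genuinely has a single valley per
  # stride in this regime (a peak/valley pair merges and vanishes)
  dex <- dense_extrema(function(tt) 20 * sin(4 * pi * f * tt) +
                         50 * sin(2 * pi * f * tt), 2, 2 + 3 / f)
  expect_equal(sum(dex$kind == "valley"), 3)   # one per stride

  rob <- robust_extrema(v, f)
  segs <- segment_strides(rob, v)
  expect_gt(length(segs), 5)
  # every segment has its two peaks and two valleys in stride order
  for (s in segs) {
    expect_true(s$p1$t < s$v1$t && s$v1$t < s$p2$t && s$p2$t < s$v2$t)
  }
  # per stride: exactly 2 peaks + 2 valleys from the robust method
  per_stride <- nrow(rob) / ((max(rob$t) - min(rob$t)) * f)
  expect_equal(per_stride, 4, tolerance = 0.15)
})

test_that("the 50 ms refinement window finds the displaced raw extremum", {
  rate <- 200; f <- 1.4
  t <- seq(0, 10, by = 1 / rate)
  y <- 36 * sin(4 * pi * f * t) + 6 * sin(2 * pi * f * t + 0.4)
  v <- vd_signal(y, rate, "head", "mc")
  attr(v, "edge_s") <- 1.5 / f
  rob <- robust_extrema(v, f)
  # oracle: dense-grid extrema of the full signal
  dex <- dense_extrema(function(tt) 36 * sin(4 * pi * f * tt) +
                         6 * sin(2 * pi * f * tt + 0.4),
                       min(rob$t) - 0.1, max(rob$t) + 0.1)
  for (i in seq_len(nrow(rob))) {
    cand <- dex[dex$kind == rob$kind[i], ]
    expect_lt(min(abs(cand$t - rob$t[i])), 1.5 / rate)
  }
})

test_that("segmentation advances two peaks per stride and trims leading valleys", {
  mk_ex <- function(kinds) {
    data.frame(t = seq_along(kinds), y = ifelse(kinds == "peak", 10, -10),
               kind = kinds)
  }
  pv <- function(n) rep(c("peak", "valley"), length.out = n)
  expect_length(segment_strides(mk_ex(pv(5))), 1)
  expect_length(segment_strides(mk_ex(pv(9))), 2)
  expect_length(segment_strides(mk_ex(pv(8))), 1)
  # leading valley dropped
  vf <- c("valley", pv(9))
  expect_length(segment_strides(mk_ex(vf)), 2)
  # too few extrema: no segments
  expect_length(segment_strides(mk_ex(pv(4))), 0)
})

test_that("stride metrics follow the printed definitions exactly", {
  m1 <- stride_metrics(mk_segment(0, 1, p1 = 30, v1 = -30, p2 = 30, v2 = -30))
  expect_equal(m1$MinDiff, 0)
  expect_equal(m1$MaxDiff, 0)
  expect_equal(m1$R, 60)
  expect_equal(m1$V, 0)
  expect_equal(m1$P, 0)

  m2 <- stride_metrics(mk_segment(0, 1, p1 = 40, v1 = -30, p2 = 30, v2 = -20))
  expect_equal(m2$MinDiff, 10)
  expect_equal(m2$MaxDiff, 10)
  expect_equal(m2$R, 70)
  expect_equal(m2$V, 10 / 70)
  expect_equal(m2$P, 10 / 70)

  m3 <- stride_metrics(mk_segment(0, 1, p1 = 30, v1 = -20, p2 = 40, v2 = -30))
  expect_equal(m3$MinDiff, -10)
  expect_equal(m3$MaxDiff, -10)
  expect_equal(m3$V, -1 / 7)
  expect_equal(m3$P, -1 / 7)

  expect_error(stride_metrics(mk_segment(0, 1, p1 = -40, v1 = 0, p2 = -50,
                                         v2 = 0)), "degenerate")
})

test_that("metrics are shift-invariant and scale-equivariant; |V|,|P| <= 1", {
  set.seed(7)
  for (i in 1:25) {
    ys <- sort(stats::rnorm(4, 0, 30))
    seg <- mk_segment(0, 1, p1 = ys[3], v1 = ys[1], p2 = ys[4], v2 = ys[2])
    m <- stride_metrics(seg)
    expect_lte(abs(m$V), 1)
    expect_lte(abs(m$P), 1)

    shift <- mk_segment(0, 1, p1 = ys[3] + 17, v1 = ys[1] + 17,
                        p2 = ys[4] + 17, v2 = ys[2] + 17)
    expect_equal(stride_metrics(shift), m)

    sc <- mk_segment(0, 1, p1 = ys[3] * 2.5, v1 = ys[1] * 2.5,
                     p2 = ys[4] * 2.5, v2 = ys[2] * 2.5)
    ms <- stride_metrics(sc)
    expect_equal(ms$MinDiff, m$MinDiff * 2.5)
    expect_equal(ms$R, m$R * 2.5)
    expect_equal(ms$V, m$V)
    expect_equal(ms$P, m$P)
  }
})

test_that("the pipeline recovers the latent NEVd on noiseless signals", {
  cfg <- trot_config(asym_v = 0.25, asym_p = -0.15, n_strides = 14,
                     noise_sd = c(mc = 0, sc = 0), stride_jitter = 0,
                     drift = 0, glitch_frac = 0, seed = 8)
  sim <- generate_trial(cfg)
  fi <- stride_frequency(sim$recording, "sc")
  an <- analyze_system(sim$recording, "mc", f_info = fi)
  truth <- sim$truth$head[1, ]  # identical for all strides (no jitter)
  expect_equal(mean(an$head$metrics$V), truth$V, tolerance = 0.01)
  expect_equal(mean(an$head$metrics$P), truth$P, tolerance = 0.01)
  expect_equal(mean(an$head$metrics$R), truth$R, tolerance = 2)
})
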