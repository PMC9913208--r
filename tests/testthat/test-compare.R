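# Agreement statistics: deviations, summaries, RMSD, Bland-Altman.

test_that("stride deviations rescale normalised differences by the mc range", {
  mc <- data.frame(V = c(0.05, 0.05), P = c(0.05, 0.05), R = c(80, 60))
  sc <- data.frame(V = c(0.10, 0.05), P = c(0.05, -0.05), R = c(75, 62))
  d <- stride_deviations(mc, sc)
  expect_equal(d$dV, c(4.0, 0))
  expect_equal(d$dP, c(0, -6.0))

  ident <- stride_deviations(mc, mc)
  expect_equal(ident$dV, c(0, 0))
  expect_equal(ident$dP, c(0, 0))
})

test_that("trial summary reproduces hand-computed means and sample SDs", {
  # 12 strides alternating V = 0.1, 0.2 with mean mc range 100
  V <- rep(c(0.1, 0.2), 6)
  mc <- data.frame(V = V, P = V, R = rep(100, 12))
  sc <- mc
  ts <- trial_summary(mc, sc, "t")
  expect_equal(ts$N, 12)
  expect_equal(ts$Vmc, 15.0)
  # hand-computed sample SD of {10,20} x 6: sqrt(300/11)
  expect_equal(ts$sVmc, sqrt(300 / 11), tolerance = 1e-12)
  expect_equal(ts$sVmc, 5.22, tolerance = 0.005)
  expect_equal(ts$dV, 0)
  expect_equal(ts$dP, 0)
  expect_equal(ts$sVsc, ts$sVmc)
})

test_that("dataset summary implements the absolute pooled deviations", {
  one <- data.frame(dV = 1, dP = -3)
  ds <- dataset_summary(one)
  expect_equal(ds$Dbar, 2)
  expect_equal(ds$maxD, 3)
  expect_equal(ds$minD, 1)
  expect_error(dataset_summary(one[0, ]), "at least one")
})

test_that("the bundled tables reproduce the published dataset summaries", {
  head_ds <- dataset_summary(load_trial_tables("head"))
  pelvis_ds <- dataset_summary(load_trial_tables("pelvis"))
  expect_equal(round(head_ds$Dbar, 1), 2.2)
  expect_equal(round(pelvis_ds$Dbar, 1), 2.2)
  expect_equal(head_ds$maxD, 8.7)
  expect_equal(pelvis_ds$maxD, 6.5)
  expect_equal(head_ds$minD, 0.0)
  expect_equal(pelvis_ds$minD, 0.0)
})

rmsd_test_segment <- function(scale = 1, offset = 0, n = 100) {
  t <- seq(0, 1, length.out = n)
  y <- (40 * sin(4 * pi * t - pi / 2)) * scale + offset
  structure(list(t_start = 0, t_end = 1, t = t, y = y,
                 p1 = list(t = 0.25, y = max(y)),
                 v1 = list(t = 0.5, y = min(y)),
                 p2 = list(t = 0.75, y = max(y)),
                 v2 = list(t = 1, y = min(y))),
            class = "stride_segment")
}

test_that("waveform RMSD is zero for identical and purely rescaled curves", {
  a <- rmsd_test_segment()
  expect_equal(rmsd_pair(a, a), 0)
  # sc = mc scaled by 2: the R-ratio correction cancels pure scaling
  expect_equal(rmsd_pair(a, rmsd_test_segment(scale = 2)), 0,
               tolerance = 1e-9)
  # constant 3 mm offset with equal ranges: closed form RMSD = 3
  expect_equal(rmsd_pair(a, rmsd_test_segment(offset = 3)), 3,
               tolerance = 1e-9)
})

test_that("RMSD ignores common offsets and cancels per-system scale", {
  set.seed(3)
  t <- seq(0, 1, length.out = 120)
  base <- 40 * sin(4 * pi * t - pi / 2)
  seg <- function(y) {
    structure(list(t_start = 0, t_end = 1, t = t, y = y,
                   p1 = list(t = t[which.max(y[1:40])], y = max(y[1:40])),
                   v1 = list(t = 0.5, y = min(y)),
                   p2 = list(t = 0.75, y = max(y[60:100])),
                   v2 = list(t = 1, y = y[120])),
              class = "stride_segment")
  }
  a <- seg(base)
  # phase-shifted partner with identical range of motion, so the scale
  # correction is exactly 1 and shift invariance is exact
  b <- seg(40 * sin(4 * pi * t - pi / 2 + 0.25))
  r0 <- rmsd_pair(a, b)
  expect_gt(r0, 0)
  # adding the same constant to both signals changes nothing
  expect_equal(rmsd_pair(seg(base + 25), seg(b$y + 25)), r0,
               tolerance = 1e-6)
  # scaling one system is cancelled by the R-ratio correction
  expect_equal(rmsd_pair(a, seg(b$y * 3)),
               rmsd_pair(a, b), tolerance = 1e-9)
  # a common positive scale rescales the deviation with the signals
  expect_equal(rmsd_pair(seg(base * 1.7), seg(b$y * 1.7)), r0 * 1.7,
               tolerance = 1e-6)
})

test_that("Bland-Altman statistics match hand computations", {
  a <- 1:10
  expect_error(bland_altman(1, 1), "at least 2")

  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_high - ba0$loa_low, 0)

  # d = {+1, -1} repeated 10x: sample SD of the 20-vector
  x <- rep(c(1, -1), 10)
  ba <- bland_altman(x, rep(0, 20))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(20 / 19), tolerance = 1e-12)
  expect_equal(ba$sd, 1.026, tolerance = 0.001)
  expect_equal(ba$loa_high, 1.96 * sqrt(20 / 19))

  b <- a + 5
  ba2 <- bland_altman(a, b)
  expect_equal(ba2$bias, -5)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)

  # antisymmetry
  set.seed(11)
  u <- rnorm(15); w <- rnorm(15)
  expect_equal(bland_altman(u, w)$bias, -bland_altman(w, u)$bias)
})

test_that("dataset deviations grow with independent per-system noise", {
  dbar_at <- function(noise) {
    vals <- vapply(1:5, function(seed) {
      cfg <- trot_config(n_strides = 12, seed = seed + 70,
                         noise_sd = c(mc = noise, sc = noise),
                         glitch_frac = 0)
      cmp <- compare_trial(generate_trial(cfg)$recording)
      dataset_summary(cmp$head$summary)$Dbar
    }, 0)
    mean(vals)
  }
  d <- vapply(c(0, 2, 5, 10), dbar_at, 0)
  expect_true(all(diff(d) > 0))
})
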