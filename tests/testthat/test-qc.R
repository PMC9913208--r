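# Stride- and trial-level quality control.

# builds a stride_segment with a raw two-harmonic slice, optionally with a
# burst injected into one quarter
qc_segment <- function(rate, f = 1.4, burst_quarter = NULL, burst_freq = 15,
                       burst_amp = 108) {
  t <- seq(0, 1 / f, by = 1 / rate)
  y <- 36 * sin(4 * pi * f * t) + 8 * sin(2 * pi * f * t + 0.3)
  if (!is.null(burst_quarter)) {
    T4 <- 1 / f / 4
    i <- which(t >= (burst_quarter - 1) * T4 & t < burst_quarter * T4)
    ph <- (t[i] - min(t[i])) / T4
    y[i] <- y[i] + burst_amp * sin(2 * pi * burst_freq * t[i]) * sin(pi * ph)^2
  }
  structure(list(t_start = 0, t_end = 1 / f, t = t, y = y, y_raw = y,
                 rate = rate,
                 p1 = list(t = 1 / (8 * f), y = max(y)),
                 v1 = list(t = 3 / (8 * f), y = min(y)),
                 p2 = list(t = 5 / (8 * f), y = max(y)),
                 v2 = list(t = 7 / (8 * f), y = min(y))),
            class = "stride_segment")
}

test_that("clean two-harmonic strides pass the high-frequency screen", {
  expect_false(flag_hf_noise(qc_segment(200)))
  expect_false(flag_hf_noise(qc_segment(60)))
})

test_that("quarter-stride bursts above 10 Hz are flagged at both rates", {
  s200 <- qc_segment(200, burst_quarter = 2, burst_freq = 15)
  expect_true(flag_hf_noise(s200))
  s60 <- qc_segment(60, burst_quarter = 2, burst_freq = 25)
  expect_true(flag_hf_noise(s60))

  # brute-force DFT oracle confirms the burst dominates above 10 Hz in
  # that quarter
  q <- function(seg, k) {
    n <- length(seg$y_raw)
    b <- floor(seq(0, n, length.out = 5))
    seg$y_raw[(b[k] + 1):b[k + 1]]
  }
  sp <- dft_power_split(q(s200, 2), 200, 10)
  expect_gt(sp[["hf"]], sp[["lf"]])
  sp_clean <- dft_power_split(q(qc_segment(200), 3), 200, 10)
  expect_lt(sp_clean[["hf"]], sp_clean[["lf"]])
})

test_that("segments too short to judge are rejected by default", {
  s <- qc_segment(200)
  s$y_raw <- s$y_raw[1:6]
  expect_true(flag_hf_noise(s))
})

test_that("outlier removal keeps tight clouds and drops gross outliers", {
  feat <- function(n, sd = 1) {
    set.seed(99)
    data.frame(MinDiff = rnorm(n, 0, sd), MaxDiff = rnorm(n, 0, sd),
               d1 = rnorm(n, 60, sd), d2 = rnorm(n, 60, sd))
  }
  # identical vectors: nothing removed (singular scatter fallback)
  same <- data.frame(MinDiff = rep(1, 20), MaxDiff = rep(2, 20),
                     d1 = rep(60, 20), d2 = rep(61, 20))
  expect_equal(remove_outliers(same), 1:20)

  # one point at 10 SD on d1 is removed; the tight cloud survives
  # (a 97.5% cut on 19 draws may shave the odd borderline inlier)
  f1 <- feat(19)
  f1 <- rbind(f1, data.frame(MinDiff = 0, MaxDiff = 0, d1 = 70, d2 = 60))
  kept <- remove_outliers(f1)
  expect_false(20 %in% kept)
  expect_gte(length(intersect(1:19, kept)), 17)

  # fewer than 8 strides: no removal regardless of spread
  f2 <- feat(5)
  f2 <- rbind(f2, data.frame(MinDiff = 100, MaxDiff = -100, d1 = 500,
                             d2 = -3))
  expect_equal(remove_outliers(f2), 1:6)
})

test_that("outlier removal is permutation-equivariant and capped at 20%", {
  set.seed(42)
  base <- data.frame(MinDiff = rnorm(30), MaxDiff = rnorm(30),
                     d1 = rnorm(30, 60), d2 = rnorm(30, 60))
  base[1:10, ] <- base[1:10, ] + 40  # a third of points far away
  kept <- remove_outliers(base)
  expect_gte(length(kept), 24)  # at most 20% of 30 = 6 removed

  perm <- sample(30)
  kept_p <- remove_outliers(base[perm, ])
  expect_setequal(perm[kept_p], kept)
})

test_that("trials below 10 matched strides on either part are excluded from both", {
  counts <- data.frame(
    trial_id = rep(c("a", "b", "c"), each = 2),
    part = rep(c("head", "pelvis"), 3),
    n = c(12, 11, 25, 9, 10, 10))
  inc <- exclude_trials(counts)
  expect_setequal(inc, c("a", "c"))  # b: pelvis 9 kills both parts
})

test_that("planted glitch strides are flagged and clean strides spared", {
  rates <- vapply(1:10, function(seed) {
    cfg <- trot_config(n_strides = 20, glitch_frac = 0.1, seed = seed)
    sim <- generate_trial(cfg)
    v <- sim$recording$signals[["sc.head"]]
    fi <- stride_frequency(sim$recording, "sc")
    bp <- bandpass_vds(v, fi$f_stride)
    ex <- robust_extrema(bp, fi$f_stride)
    segs <- segment_strides(ex, bp, raw = v)
    flagged <- vapply(segs, flag_hf_noise, TRUE)
    # world-time glitch windows, mapped to the sc clock
    g <- sim$truth$corrupted
    contaminated <- vapply(segs, function(s) {
      any(pmin(s$t_end, g$t_end - cfg$offset) -
            pmax(s$t_start, g$t_start - cfg$offset) > 0.02)
    }, TRUE)
    c(hit = mean(flagged[contaminated]), false = mean(flagged[!contaminated]))
  }, c(hit = 0, false = 0))
  expect_gte(stats::median(rates["hit", ]), 0.8)
  expect_lte(stats::median(rates["false", ]), 0.05)
})
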