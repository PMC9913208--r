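# Independent oracles and small builders used across the test files.

# Closed-form squared magnitude response of a zero-phase (forward-backward)
# Butterworth band-pass designed via prewarped bilinear transform: the
# analog prototype response evaluated at the warped frequency, squared by
# the two passes. Independent of the package's filter implementation.
bp_filtfilt_gain <- function(f, order, lo, hi, rate) {
  w <- function(fq) 2 * rate * tan(pi * fq / rate)
  W <- (w(f)^2 - w(lo) * w(hi)) / (w(f) * (w(hi) - w(lo)))
  (1 / (1 + W^(2 * order)))  # one pass |H|^2; filtfilt applies it twice
}

hp_filtfilt_gain <- function(f, order, cut, rate) {
  w <- function(fq) 2 * rate * tan(pi * fq / rate)
  W <- w(cut) / w(f)
  (1 / (1 + W^(2 * order)))
}

# least-squares amplitude of a sinusoid at frequency f in signal y(t)
fit_amplitude <- function(t, y, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  co <- qr.solve(X, y)
  sqrt(sum(co^2))
}

# brute-force DFT power split of a window at a frequency cut (oracle for
# the high-frequency dominance rule; explicit O(n^2) sum, no fft).
# Mean-removed: DC is discounted, the in-window trend counts as low-
# frequency content.
dft_power_split <- function(y, rate, cut = 10) {
  m <- length(y)
  x <- seq_len(m)
  r <- y - mean(y)
  ks <- 0:(m %/% 2)
  pw <- vapply(ks, function(k) {
    Mod(sum(r * exp(-2i * pi * k * (x - 1) / m)))^2
  }, 0)
  fr <- ks * rate / m
  c(lf = sum(pw[fr <= cut]), hf = sum(pw[fr > cut]))
}

# dense-grid extrema of a function on an interval by exhaustive local
# comparison (oracle for extremum extraction)
dense_extrema <- function(fun, from, to, dt = 1e-4) {
  t <- seq(from, to, by = dt)
  y <- fun(t)
  s <- sign(diff(y))
  i <- which(s[-length(s)] > 0 & s[-1] < 0) + 1
  j <- which(s[-length(s)] < 0 & s[-1] > 0) + 1
  rbind(data.frame(t = t[i], y = y[i], kind = "peak"),
        data.frame(t = t[j], y = y[j], kind = "valley"))
}

sine_signal <- function(f, amp = 30, rate = 60, dur = 20, keypoint = "head",
                        system = "sc", phase = 0, offset = 0) {
  t <- seq(0, dur, by = 1 / rate)
  vd_signal(amp * sin(2 * pi * f * t + phase) + offset, rate, keypoint,
            system)
}

# bare stride segment for matching / metric tests
mk_segment <- function(t_start, t_end, p1 = 30, v1 = -30, p2 = 30,
                       v2 = -30) {
  T4 <- (t_end - t_start) / 4
  structure(list(t_start = t_start, t_end = t_end,
                 p1 = list(t = t_start, y = p1),
                 v1 = list(t = t_start + T4, y = v1),
                 p2 = list(t = t_start + 2 * T4, y = p2),
                 v2 = list(t = t_start + 3 * T4, y = v2)),
            class = "stride_segment")
}

# smooth non-periodic test signal (filtered noise), for sharp unique
# cross-correlation peaks
smooth_noise_fun <- function(seed, dur = 30, knot_dt = 0.2) {
  set.seed(seed)
  kt <- seq(-5, dur + 5, by = knot_dt)
  kv <- stats::rnorm(length(kt))
  function(t) stats::spline(kt, kv, xout = t)$y * 20
}
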