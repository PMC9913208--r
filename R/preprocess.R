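# Hoof pre-filtering, stride splitting and stride-scaled band-pass
# filtering of head/pelvis signals.
#
# The hoof pre-filter uses a fixed trot band (0.6-2.2 Hz, 7th-order
# prototype); the head/pelvis band-pass is scaled to the estimated stride
# frequency (0.75 x f_stride .. 2.42 x f_stride, 10th-order prototype) so
# that the first harmonic (asymmetry-related) and second harmonic
# (symmetric movement) pass while trend and higher-frequency noise are
# removed. All filtering is zero phase (forward-backward) because peak and
# valley timing feeds the asymmetry metrics directly and causal phase
# distortion would bias them.

#' Pre-filter a hoof signal for stride splitting
#'
#' Zero-phase Butterworth band-pass (7th-order prototype, 0.6-2.2 Hz) of a
#' hoof vertical displacement signal. Removes baseline trend and
#' high-frequency noise so that left/right hoof height crossings are clean.
#'
#' @param v A hoof [vd_signal()] with `rate > 4.4` Hz.
#' @param low,high Band edges in Hz.
#' @param order Prototype filter order.
#' @return A filtered [vd_signal()]; an `edge_s` attribute flags the edge
#'   region (1.5 periods of the lower band edge at each end) where filter
#'   transients are unavoidable.
#' @export
prefilter_hoof <- function(v, low = 0.6, high = 2.2, order = 7) {
  stopifnot(inherits(v, "vd_signal"))
  if (!startsWith(v$keypoint, "hoof"))
    stop("prefilter_hoof expects a hoof signal, got ", v$keypoint)
  if (v$rate <= 2 * high) stop("sampling rate too low for the 0.6-2.2 Hz band")
  dur <- (length(v$y) - 1) / v$rate
  if (dur < 3 / low) stop("too short to filter (need 3 stride periods at ",
                          low, " Hz)")
  if (anyNA(v$y)) stop("hoof signal has gaps; fill or trim before filtering")
  sos <- butter_sos(order, v$rate, low = low, high = high, type = "pass")
  out <- vd_signal(filtfilt_sos(sos, v$y), v$rate, v$keypoint, v$system, v$t0)
  attr(out, "edge_s") <- 1.5 / low
  out
}

#' Split strides from a left/right hoof pair
#'
#' Resamples both pre-filtered hoof signals to a common grid (the finer of
#' the two rates, by linear interpolation), finds the zero crossings of
#' left minus right (the instants at which the left hoof passes the right
#' hoof in height) and estimates the stride frequency from the interval
#' lengths: one full stride spans two consecutive half-stride intervals.
#'
#' @param left,right Pre-filtered hoof [vd_signal()]s of one pair (fore or
#'   hind) from the same system with overlapping time support.
#' @param min_interval Intervals shorter than this (s) are regarded as
#'   zero-crossing chatter and merged into their neighbours.
#' @return A `stride_intervals` object: list with `boundaries` (crossing
#'   times, s), `f_stride` (Hz) and `left_above` (logical per interval:
#'   is the left hoof above the right in that interval).
#' @export
split_strides <- function(left, right, min_interval = 0.15) {
  stopifnot(inherits(left, "vd_signal"), inherits(right, "vd_signal"))
  if (left$system != right$system)
    stop("hoof pair must come from the same system")
  rate <- max(left$rate, right$rate)
  t_lo <- max(min(vd_time(left)), min(vd_time(right)))
  t_hi <- min(max(vd_time(left)), max(vd_time(right)))
  if (t_hi - t_lo < 2 / rate) stop("hoof signals do not overlap in time")
  grid <- seq(t_lo, t_hi, by = 1 / rate)
  li <- stats::approx(vd_time(left), left$y, grid)$y
  ri <- stats::approx(vd_time(right), right$y, grid)$y
  d <- li - ri

  s <- sign(d)
  s[s == 0] <- 1
  ch <- which(diff(s) != 0)
  if (length(ch) < 4) stop("insufficient strides (fewer than 4 left/right crossings)")
  # linear interpolation of each crossing instant
  cross <- grid[ch] + (0 - d[ch]) / (d[ch + 1] - d[ch]) / rate

  # merge chatter: drop crossing pairs bounding intervals < min_interval
  repeat {
    len <- diff(cross)
    short <- which(len < min_interval)
    if (!length(short) || length(cross) <= 2) break
    i <- short[which.min(len[short])]
    # dropping both endpoints of a chatter interval merges its neighbours;
    # at the ends, drop the outer crossing only
    drop <- if (i == 1) 1 else if (i == length(cross) - 1) length(cross)
            else c(i, i + 1)
    cross <- cross[-drop]
  }
  if (length(cross) < 4) stop("insufficient strides (fewer than 4 left/right crossings)")

  mid <- (cross[-length(cross)] + cross[-1]) / 2
  left_above <- stats::approx(grid, d, mid)$y > 0
  stride_len <- diff(cross, lag = 2)
  f_stride <- 1 / mean(stride_len)
  structure(list(boundaries = cross, f_stride = f_stride,
                 left_above = left_above),
            class = "stride_intervals")
}

#' @export
print.stride_intervals <- function(x, ...) {
  cat(sprintf("<stride_intervals> %d crossings, f_stride = %.3f Hz\n",
              length(x$boundaries), x$f_stride))
  invisible(x)
}

#' Estimate stride frequency for a recording
#'
#' Pre-filters the available hoof signals of one system and combines the
#' fore (LF/RF) and hind (LH/RH) pair estimates: the mean when both are
#' available, else whichever exists.
#'
#' @param recording A [trial_recording()].
#' @param system System whose hooves to use (hooves are typically observed
#'   by the single camera only).
#' @return List with `f_stride` (Hz) and `intervals` (the
#'   [split_strides()] result of the fore pair when available, else hind).
#' @export
stride_frequency <- function(recording, system = "sc") {
  pairs <- list(fore = c("hoof_lf", "hoof_rf"), hind = c("hoof_lh", "hoof_rh"))
  ests <- list()
  for (nm in names(pairs)) {
    l <- get_signal(recording, system, pairs[[nm]][1])
    r <- get_signal(recording, system, pairs[[nm]][2])
    if (is.null(l) || is.null(r)) next
    ests[[nm]] <- split_strides(prefilter_hoof(l), prefilter_hoof(r))
  }
  if (!length(ests))
    stop("cannot estimate stride frequency: no complete hoof pair for system '",
         system, "'")
  f <- mean(vapply(ests, function(e) e$f_stride, 0))
  list(f_stride = f, intervals = ests[[1]])
}

#' Stride-frequency-scaled band-pass of a head or pelvis signal
#'
#' Zero-phase Butterworth band-pass (10th-order prototype) on
#' `[0.75 f_stride, 2.42 f_stride]`: the first and second stride harmonics
#' pass essentially unattenuated while baseline wander and third and
#' higher harmonics are removed.
#'
#' @param v A head or pelvis [vd_signal()].
#' @param f_stride Stride frequency in Hz.
#' @param lo_mult,hi_mult Band-edge multipliers of `f_stride`.
#' @param order Prototype filter order.
#' @return Filtered [vd_signal()] with an `edge_s` attribute of
#'   `1.5 / f_stride` seconds flagging the transient region at each end.
#'   Gap runs (`NA`) are filtered per contiguous run; runs shorter than
#'   three stride periods are left as gaps.
#' @export
bandpass_vds <- function(v, f_stride, lo_mult = 0.75, hi_mult = 2.42,
                         order = 10) {
  stopifnot(inherits(v, "vd_signal"))
  if (!v$keypoint %in% c("head", "pelvis"))
    stop("bandpass_vds expects a head or pelvis signal, got ", v$keypoint)
  if (f_stride <= 0) stop("f_stride must be positive")
  hi <- hi_mult * f_stride
  if (hi >= v$rate / 2)
    stop(sprintf(paste0("upper band edge %.2f Hz violates the Nyquist limit ",
                        "%.2f Hz; resample the signal to a higher rate"),
                 hi, v$rate / 2))
  sos <- butter_sos(order, v$rate, low = lo_mult * f_stride, high = hi,
                    type = "pass")
  y <- rep(NA_real_, length(v$y))
  min_run <- ceiling(3 / f_stride * v$rate)
  for (run in na_runs(v$y)) {
    if (run[2] - run[1] + 1 < min_run) next
    idx <- run[1]:run[2]
    y[idx] <- filtfilt_sos(sos, v$y[idx])
  }
  if (all(is.na(y)))
    stop("no contiguous run of 3 stride periods to filter")
  out <- vd_signal(y, v$rate, v$keypoint, v$system, v$t0)
  attr(out, "edge_s") <- 1.5 / f_stride
  out
}

# contiguous non-NA index runs, as list of c(start, end)
na_runs <- function(y) {
  ok <- !is.na(y)
  if (!any(ok)) return(list())
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  lapply(keep, function(i) c(starts[i], ends[i]))
}
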