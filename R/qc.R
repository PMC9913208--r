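# Stride- and trial-level quality control.
#
# Two stride-level screens: (1) a spectral rule that rejects strides whose
# high-frequency (> 10 Hz) spectral content dominates in at least one
# quarter of the stride interval, and (2) a robust multivariate outlier
# rule on the four per-stride features MinDiff, MaxDiff, p1 - v1, p2 - v2.
# Trial-level: a trial is excluded from all analyses when any body part
# retains fewer than 10 matched strides.

#' Flag a stride segment contaminated by high-frequency noise
#'
#' The raw stride slice is split at `hf_cut` Hz into a low and a high
#' component with a zero-phase Butterworth low-pass over the whole
#' segment (a quarter-stride window is far too short to resolve a 10 Hz
#' boundary by windowed DFT: at typical stride frequencies its bin width
#' exceeds 5 Hz and the trot harmonics leak above the cut). The segment
#' is then divided into four equal-length windows; a window is "noisy"
#' when the high-component power in it exceeds the mean-removed power of
#' the low component — the Parseval-consistent reading of "the majority
#' of the frequency content". Only the constant level is discounted from
#' the low side: the within-window trend of the displacement curve is
#' genuine sub-10 Hz signal content (a quarter stride is roughly one
#' monotone half-lobe of the second harmonic, so detrending it away
#' would leave almost nothing to compare against). The stride is
#' rejected when at least one window is noisy. The check runs on the
#' segment's raw sample slice (`y_raw`) when available, because
#' band-pass filtering removes the very content the rule looks for.
#'
#' @param seg A `stride_segment` carrying its sample slice.
#' @param rate Sampling rate in Hz (defaults to the segment's); must
#'   exceed `2 * hf_cut` so the cut frequency is representable.
#' @param hf_cut High-frequency threshold in Hz.
#' @param n_windows Number of equal windows per stride.
#' @return `TRUE` if the stride should be rejected.
#' @export
flag_hf_noise <- function(seg, rate = NULL, hf_cut = 10, n_windows = 4) {
  stopifnot(inherits(seg, "stride_segment"))
  if (is.null(rate)) rate <- seg$rate
  if (is.null(rate)) stop("segment carries no rate; pass `rate`")
  if (rate <= 2 * hf_cut)
    stop("sampling rate must exceed ", 2 * hf_cut, " Hz for the ", hf_cut,
         " Hz noise rule")
  y <- seg$y_raw %||% seg$y
  y <- y[!is.na(y)]
  n <- length(y)
  if (n < 2 * n_windows || n < 8) return(TRUE)  # too short to judge: reject
  sos <- butter_sos(4, rate, high = hf_cut, type = "low")
  lo <- filtfilt_sos(sos, y)
  hi <- y - lo
  bounds <- floor(seq(0, n, length.out = n_windows + 1))
  for (w in seq_len(n_windows)) {
    idx <- (bounds[w] + 1):bounds[w + 1]
    if (length(idx) < 4) return(TRUE)
    lo_c <- lo[idx] - mean(lo[idx])
    if (sum(hi[idx]^2) > sum(lo_c^2)) return(TRUE)
  }
  FALSE
}

#' Per-stride outlier features
#'
#' Represents each stride by the four peak/valley differences used for
#' multivariate outlier screening: `MinDiff`, `MaxDiff`, `d1 = p1 - v1`
#' and `d2 = p2 - v2`.
#'
#' @param segments List of `stride_segment`s.
#' @return Data frame with columns `MinDiff`, `MaxDiff`, `d1`, `d2` (mm).
#' @export
stride_features <- function(segments) {
  if (!length(segments))
    return(data.frame(MinDiff = numeric(0), MaxDiff = numeric(0),
                      d1 = numeric(0), d2 = numeric(0)))
  do.call(rbind, lapply(segments, function(s)
    data.frame(MinDiff = s$v2$y - s$v1$y, MaxDiff = s$p1$y - s$p2$y,
               d1 = s$p1$y - s$v1$y, d2 = s$p2$y - s$v2$y)))
}

#' Remove outlier strides in feature space
#'
#' Computes a robust squared Mahalanobis distance for each stride's
#' four-feature vector: location and scatter are estimated from the
#' central 75% of strides (those with the smallest classical distances),
#' and strides whose robust squared distance exceeds the chi-squared(4)
#' quantile `chi2_q` are removed, largest first, with at most
#' `max_frac` of strides removed. Below `min_n` strides no removal is
#' attempted (too few for covariance estimation). If the scatter matrix
#' is singular the rule falls back to per-feature robust z-scores
#' (|median-centred value| / (1.4826 MAD) > 3.5 on any feature).
#'
#' @param features Data frame from [stride_features()].
#' @param chi2_q Chi-squared quantile for the cut-off.
#' @param max_frac Maximum fraction of strides removed.
#' @param min_n Minimum stride count for any removal.
#' @return Integer vector of kept row indices.
#' @export
remove_outliers <- function(features, chi2_q = 0.975, max_frac = 0.2,
                            min_n = 8) {
  X <- as.matrix(features[, c("MinDiff", "MaxDiff", "d1", "d2")])
  n <- nrow(X)
  if (n < min_n) return(seq_len(n))

  d2 <- tryCatch({
    mu0 <- colMeans(X)
    S0 <- stats::cov(X)
    d0 <- stats::mahalanobis(X, mu0, S0)
    h <- ceiling(0.75 * n)
    core <- order(d0)[seq_len(h)]
    mu <- colMeans(X[core, , drop = FALSE])
    S <- stats::cov(X[core, , drop = FALSE])
    # consistency correction: a covariance from the central 75% of a
    # Gaussian underestimates scatter and would inflate every distance
    p <- ncol(X)
    cc <- (h / n) / stats::pchisq(stats::qchisq(h / n, p), p + 2)
    stats::mahalanobis(X, mu, S * cc)
  }, error = function(e) NULL)

  cut <- stats::qchisq(chi2_q, df = ncol(X))
  if (is.null(d2) || !all(is.finite(d2))) {
    # singular scatter: per-feature robust z-scores
    z <- apply(X, 2, function(col) {
      med <- stats::median(col)
      s <- stats::mad(col)
      dev <- abs(col - med)
      ifelse(dev == 0, 0, ifelse(s == 0, Inf, dev / s))
    })
    score <- apply(z, 1, max)
    bad <- which(score > 3.5)
  } else {
    score <- d2
    bad <- which(d2 > cut)
  }
  max_rm <- floor(max_frac * n)
  if (length(bad) > max_rm)
    bad <- bad[order(score[bad], decreasing = TRUE)][seq_len(max_rm)]
  setdiff(seq_len(n), bad)
}

#' Trial-level exclusion by matched stride count
#'
#' A trial is excluded from the analyses of *all* body parts when any
#' part has fewer than `min_strides` matched strides after outlier
#' removal ("less than 10" excludes counts of 9 and below).
#'
#' @param counts Data frame with columns `trial_id`, `part`, `n`.
#' @param min_strides Minimum matched strides per part.
#' @return Character vector of included trial ids.
#' @export
exclude_trials <- function(counts, min_strides = 10) {
  stopifnot(all(c("trial_id", "part", "n") %in% names(counts)))
  ok <- tapply(counts$n >= min_strides, counts$trial_id, all)
  names(ok)[ok]
}
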