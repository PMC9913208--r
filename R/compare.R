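# Between-system agreement: per-stride deviations, trial and dataset
# summaries, scale-corrected waveform RMSD and Bland-Altman statistics.
#
# Deviations of the normalised metrics are rescaled to millimetres
# ("geometric scale") with the reference system's range of motion, so
# agreement numbers read directly in mm of vertical displacement.

#' Per-stride between-system deviations
#'
#' For each matched stride pair, the normalised metric difference is
#' rescaled by that stride's reference range of motion:
#' `dV = (V_sc - V_mc) * R_mc`, `dP = (P_sc - P_mc) * R_mc`.
#'
#' @param mc_metrics,sc_metrics Data frames of per-stride metrics
#'   ([strides_table()] rows), aligned row-by-row over matched pairs.
#' @return Data frame with columns `dV`, `dP` (mm) and `R_mc`.
#' @export
stride_deviations <- function(mc_metrics, sc_metrics) {
  stopifnot(nrow(mc_metrics) == nrow(sc_metrics))
  data.frame(dV = (sc_metrics$V - mc_metrics$V) * mc_metrics$R,
             dP = (sc_metrics$P - mc_metrics$P) * mc_metrics$R,
             R_mc = mc_metrics$R)
}

#' Trial-level summary of matched strides
#'
#' Rescales each system's normalised per-stride values by the trial-mean
#' reference range of motion `Rbar_mc` and summarises: per-system means
#' and sample standard deviations of `V * Rbar_mc` and `P * Rbar_mc`, and
#' the trial-mean deviations `dV = Vsc - Vmc`, `dP = Psc - Pmc` (mm).
#'
#' @param mc_metrics,sc_metrics Aligned per-stride metric tables of the
#'   matched, QC-passing strides of one trial.
#' @param trial_id Identifier stored in the output row.
#' @return One-row data frame shaped like the bundled reference tables:
#'   `trial_id`, `N`, `dV`, `dP`, `Vsc`, `Vmc`, `Psc`, `Pmc`, `sVsc`,
#'   `sVmc`, `sPsc`, `sPmc`, `Rmc`.
#' @export
trial_summary <- function(mc_metrics, sc_metrics, trial_id = "trial") {
  stopifnot(nrow(mc_metrics) == nrow(sc_metrics))
  N <- nrow(mc_metrics)
  if (N < 2) stop("trial summary needs at least 2 matched strides")
  Rbar <- mean(mc_metrics$R)
  g <- function(x) x * Rbar
  Vsc <- g(sc_metrics$V); Vmc <- g(mc_metrics$V)
  Psc <- g(sc_metrics$P); Pmc <- g(mc_metrics$P)
  data.frame(trial_id = trial_id, N = N,
             dV = mean(Vsc) - mean(Vmc), dP = mean(Psc) - mean(Pmc),
             Vsc = mean(Vsc), Vmc = mean(Vmc),
             Psc = mean(Psc), Pmc = mean(Pmc),
             sVsc = stats::sd(Vsc), sVmc = stats::sd(Vmc),
             sPsc = stats::sd(Psc), sPmc = stats::sd(Pmc),
             Rmc = Rbar)
}

#' Dataset-level absolute deviation summary
#'
#' Pools the per-trial mean deviations of both metrics:
#' `Dbar = (sum |dV_m| + sum |dP_m|) / (2 M)`, with `maxD` and `minD` the
#' extremes over the union of the absolute `dV` and `dP` values.
#'
#' @param trials Data frame with per-trial columns `dV` and `dP` (mm).
#' @return One-row data frame with `Dbar`, `maxD`, `minD` (mm) and `M`
#'   (number of trials).
#' @export
dataset_summary <- function(trials) {
  stopifnot(all(c("dV", "dP") %in% names(trials)))
  M <- nrow(trials)
  if (M < 1) stop("dataset summary needs at least one trial")
  pool <- c(abs(trials$dV), abs(trials$dP))
  data.frame(Dbar = sum(pool) / (2 * M), maxD = max(pool), minD = min(pool),
             M = M)
}

#' Scale-corrected waveform RMSD of one matched stride pair
#'
#' Samples each system's stride segment at `n_points` equally spaced
#' times between its own first and third peak (linear interpolation of
#' the band-passed samples), multiplies the single-camera curve by
#' `R_mc / R_sc` to bring it to the reference geometric scale, and
#' returns the root mean square difference.
#'
#' @param mc_seg,sc_seg Matched `stride_segment`s carrying their sample
#'   slices.
#' @param n_points Number of resampling points per stride.
#' @return RMSD in mm, or `NA` if the sc range of motion is degenerate.
#' @export
rmsd_pair <- function(mc_seg, sc_seg, n_points = 101) {
  R_mc <- stride_metrics(mc_seg)$R
  R_sc <- tryCatch(stride_metrics(sc_seg)$R, error = function(e) 0)
  if (R_sc <= 0) return(NA_real_)
  g_mc <- seq(mc_seg$t_start, mc_seg$t_end, length.out = n_points)
  g_sc <- seq(sc_seg$t_start, sc_seg$t_end, length.out = n_points)
  y_mc <- stats::approx(mc_seg$t, mc_seg$y, g_mc)$y
  y_sc <- stats::approx(sc_seg$t, sc_seg$y, g_sc)$y * (R_mc / R_sc)
  sqrt(mean((y_sc - y_mc)^2))
}

#' Mean waveform RMSD over matched pairs
#'
#' @param mc_segments,sc_segments Aligned lists of matched
#'   `stride_segment`s.
#' @param n_points Resampling points per stride.
#' @return Mean of the per-pair [rmsd_pair()] values (mm), skipping
#'   degenerate pairs.
#' @export
rmsd_trial <- function(mc_segments, sc_segments, n_points = 101) {
  stopifnot(length(mc_segments) == length(sc_segments))
  vals <- mapply(rmsd_pair, mc_segments, sc_segments,
                 MoreArgs = list(n_points = n_points))
  mean(vals, na.rm = TRUE)
}

#' Bland-Altman agreement statistics
#'
#' Differences `d = a - b`: bias is their mean and the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)` (sample standard deviation).
#'
#' @param a,b Paired numeric vectors (same length, `n >= 2`).
#' @return A `bland_altman` object: list with `bias`, `loa_low`,
#'   `loa_high`, `sd`, `n`, and `means`/`diffs` for plotting.
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  structure(list(bias = mean(d), sd = s,
                 loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s,
                 n = n, means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias = %.3f, LoA = [%.3f, %.3f]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#' @param x A `bland_altman` object.
#' @param ... Passed to [plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs, xlab = "mean of systems (mm)",
                 ylab = "difference (mm)", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high),
                   lty = c(2, 1, 2), col = c("orange", "black", "orange"))
  invisible(x)
}
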