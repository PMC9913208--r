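# Per-stride peak/valley extraction and asymmetry metrics.
#
# At trot, the head/pelvis vertical displacement traces a double sinusoid
# per stride: two peaks and two valleys. The signed differences between
# the two valleys (MinDiff, impact asymmetry) and the two peaks (MaxDiff,
# push-off asymmetry) are the lameness indicators; dividing by the stride
# range of motion R gives the normalised extreme-value differences (NEVd)
# V and P, which are comparable across horses of different size.

#' Extract alternating local extrema of a filtered signal
#'
#' Compares consecutive samples to locate points of zero derivative.
#' Plateaus of equal samples yield one extremum at the plateau midpoint.
#' The sequence is then reduced to strict peak/valley alternation by
#' keeping the most extreme member of any same-kind run. Extrema inside
#' the edge-transient region (the signal's `edge_s` attribute, set by the
#' filters) are dropped.
#'
#' @param v A band-pass filtered [vd_signal()] (gap-free in the region of
#'   interest).
#' @param edge_s Edge exclusion in seconds at each end; defaults to the
#'   signal's `edge_s` attribute (0 if unset).
#' @return Data frame with columns `t` (s), `y` (mm), `kind`
#'   (`"peak"`/`"valley"`), time-ordered and alternating.
#' @export
extract_extrema <- function(v, edge_s = NULL) {
  stopifnot(inherits(v, "vd_signal"))
  if (is.null(edge_s)) edge_s <- attr(v, "edge_s") %||% 0
  tt <- vd_time(v)
  ex <- local_extrema(tt, v$y)
  lo <- min(tt, na.rm = TRUE) + edge_s
  hi <- max(tt, na.rm = TRUE) - edge_s
  ex <- ex[ex$t >= lo & ex$t <= hi, , drop = FALSE]
  ex <- enforce_alternation(ex)
  if (nrow(ex) < 4) stop("no complete stride (fewer than 4 extrema)")
  rownames(ex) <- NULL
  ex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# raw local extrema with plateau-midpoint rule; NA-safe (per non-NA run)
local_extrema <- function(tt, y) {
  out <- list()
  for (run in na_runs(y)) {
    idx <- run[1]:run[2]
    if (length(idx) < 3) next
    yr <- y[idx]; tr <- tt[idx]
    s <- sign(diff(yr))
    nz <- which(s != 0)
    if (length(nz) < 2) next
    for (k in seq_len(length(nz) - 1)) {
      i <- nz[k]; j <- nz[k + 1]
      if (s[i] == s[j]) next
      out[[length(out) + 1]] <- data.frame(
        t = (tr[i + 1] + tr[j]) / 2,  # plateau i+1..j (j = i for strict)
        y = yr[i + 1],
        kind = if (s[i] > 0) "peak" else "valley")
    }
  }
  if (!length(out))
    return(data.frame(t = numeric(0), y = numeric(0), kind = character(0)))
  ex <- do.call(rbind, out)
  ex[order(ex$t), , drop = FALSE]
}

# keep the most extreme of any run of same-kind extrema
enforce_alternation <- function(ex) {
  if (nrow(ex) < 2) return(ex)
  keep <- rep(TRUE, nrow(ex))
  i <- 1
  while (i < nrow(ex)) {
    j <- i
    while (j < nrow(ex) && ex$kind[j + 1] == ex$kind[i]) j <- j + 1
    if (j > i) {
      run <- i:j
      best <- if (ex$kind[i] == "peak") run[which.max(ex$y[run])]
              else run[which.min(ex$y[run])]
      keep[setdiff(run, best)] <- FALSE
    }
    i <- j + 1
  }
  ex[keep, , drop = FALSE]
}

#' Robust extrema via the second stride harmonic
#'
#' In markedly lame horses the large first harmonic can cancel one of the
#' two local extrema per stride, so plain extremum detection finds a
#' single peak or valley per stride. This method recovers the two-per-
#' stride structure: (1) high-pass the signal above the first harmonic
#' (cut-off `cut_mult * f_stride`, zero-phase Butterworth of order
#' `order`) to isolate the second-harmonic curve shape; (2) locate the
#' extrema of the filtered signal; (3) replace each candidate by the most
#' extreme value of the *original* signal within `window` seconds of the
#' candidate time.
#'
#' @param v Band-pass filtered head/pelvis [vd_signal()].
#' @param f_stride Stride frequency in Hz.
#' @param window Half-width of the refinement window in seconds (50 ms).
#' @param cut_mult High-pass cut-off as a multiple of `f_stride`; strictly
#'   above the first harmonic and well below the second.
#' @param order High-pass prototype order.
#' @param edge_s Edge exclusion (see [extract_extrema()]).
#' @return Data frame as in [extract_extrema()].
#' @export
robust_extrema <- function(v, f_stride, window = 0.050, cut_mult = 1.5,
                           order = 5, edge_s = NULL) {
  stopifnot(inherits(v, "vd_signal"))
  if (is.null(edge_s)) edge_s <- attr(v, "edge_s") %||% 0
  sos <- butter_sos(order, v$rate, low = cut_mult * f_stride, type = "high")
  hp <- v
  for (run in na_runs(v$y)) {
    idx <- run[1]:run[2]
    if (length(idx) < ceiling(2 / f_stride * v$rate)) {
      hp$y[idx] <- NA
      next
    }
    hp$y[idx] <- filtfilt_sos(sos, v$y[idx])
  }
  attr(hp, "edge_s") <- edge_s
  cand <- extract_extrema(hp, edge_s = edge_s)

  tt <- vd_time(v)
  refined <- lapply(seq_len(nrow(cand)), function(k) {
    win <- which(tt >= cand$t[k] - window & tt <= cand$t[k] + window &
                   !is.na(v$y))
    if (!length(win)) return(NULL)
    i <- if (cand$kind[k] == "peak") win[which.max(v$y[win])]
         else win[which.min(v$y[win])]
    data.frame(t = tt[i], y = v$y[i], kind = cand$kind[k])
  })
  ex <- do.call(rbind, refined)
  ex <- ex[order(ex$t), , drop = FALSE]
  ex <- ex[!duplicated(ex[, c("t", "kind")]), , drop = FALSE]
  ex <- enforce_alternation(ex)
  if (nrow(ex) < 4) stop("no complete stride (fewer than 4 extrema)")
  rownames(ex) <- NULL
  ex
}

#' Segment full strides from an alternating extremum sequence
#'
#' A stride segment spans from one peak to the second-next peak and
#' contains two peaks and two valleys
#' (`t_p1 < t_v1 < t_p2 < t_v2 < t_end`). Segments are non-overlapping:
#' consecutive segments advance two peaks, keeping per-stride samples
#' independent for the agreement statistics. A leading valley is trimmed
#' so the sequence starts at a peak.
#'
#' @param extrema Alternating extremum data frame ([extract_extrema()] or
#'   [robust_extrema()]).
#' @param v The [vd_signal()] the extrema came from; its samples are
#'   sliced into each segment (needed for waveform RMSD).
#' @param raw Optional unfiltered [vd_signal()]; its slice is stored as
#'   `y_raw` for the high-frequency noise check, which must look at
#'   content the band-pass removes.
#' @param intervals Optional [split_strides()] result used to anchor the
#'   side convention: the segmentation phase is chosen so that each
#'   segment's first valley falls in a left-hoof-above interval, making
#'   the sign of MinDiff/MaxDiff consistent across strides and trials.
#' @return List of `stride_segment` objects: each has `t_start`, `t_end`,
#'   extrema `p1`, `v1`, `p2`, `v2` (lists with `t`, `y`), and the sample
#'   slice `t`, `y`.
#' @export
segment_strides <- function(extrema, v = NULL, intervals = NULL,
                            raw = NULL) {
  ex <- extrema
  if (nrow(ex) && ex$kind[1] == "valley") ex <- ex[-1, , drop = FALSE]
  if (nrow(ex) < 5) return(list())

  build <- function(ex) {
    n_seg <- (nrow(ex) - 1) %/% 4
    segs <- vector("list", n_seg)
    for (k in seq_len(n_seg)) {
      e <- ex[(4 * k - 3):(4 * k + 1), ]
      if (!all(e$kind == c("peak", "valley", "peak", "valley", "peak")))
        return(NULL)
      seg <- list(t_start = e$t[1], t_end = e$t[5],
                  p1 = list(t = e$t[1], y = e$y[1]),
                  v1 = list(t = e$t[2], y = e$y[2]),
                  p2 = list(t = e$t[3], y = e$y[3]),
                  v2 = list(t = e$t[4], y = e$y[4]))
      if (!is.null(v)) {
        tt <- vd_time(v)
        idx <- which(tt >= seg$t_start & tt <= seg$t_end)
        seg$t <- tt[idx]
        seg$y <- v$y[idx]
        seg$rate <- v$rate
        seg$keypoint <- v$keypoint
        seg$system <- v$system
      }
      if (!is.null(raw)) {
        ttr <- vd_time(raw)
        seg$y_raw <- raw$y[ttr >= seg$t_start & ttr <= seg$t_end]
      }
      segs[[k]] <- structure(seg, class = "stride_segment")
    }
    segs
  }

  segs <- build(ex)
  if (is.null(segs)) stop("extremum sequence does not alternate")

  if (!is.null(intervals) && length(segs)) {
    frac_left <- function(segs) {
      v1 <- vapply(segs, function(s) s$v1$t, 0)
      mean(vapply(v1, function(t) in_left_interval(t, intervals), TRUE))
    }
    if (frac_left(segs) < 0.5 && nrow(ex) >= 7) {
      alt <- build(ex[-(1:2), , drop = FALSE])  # advance phase by one half-stride
      if (!is.null(alt) && length(alt) && frac_left(alt) > frac_left(segs))
        segs <- alt
    }
  }
  segs
}

in_left_interval <- function(t, intervals) {
  b <- intervals$boundaries
  i <- findInterval(t, b)
  if (i < 1 || i >= length(b)) return(NA)
  isTRUE(intervals$left_above[i])
}

#' @export
print.stride_segment <- function(x, ...) {
  cat(sprintf("<stride_segment> [%.3f, %.3f] s: p %.1f/%.1f, v %.1f/%.1f mm\n",
              x$t_start, x$t_end, x$p1$y, x$p2$y, x$v1$y, x$v2$y))
  invisible(x)
}

#' Per-stride asymmetry metrics
#'
#' Computes the signed valley difference `MinDiff = v2 - v1`, the signed
#' peak difference `MaxDiff = p1 - p2`, the range of motion
#' `R = max(p1, p2) - min(v1, v2)` and the normalised differences
#' `V = MinDiff / R`, `P = MaxDiff / R`.
#'
#' @param seg A `stride_segment`.
#' @return A one-row data frame with columns `MinDiff`, `MaxDiff`, `R`
#'   (mm) and `V`, `P` (dimensionless).
#' @export
stride_metrics <- function(seg) {
  stopifnot(inherits(seg, "stride_segment"))
  MinDiff <- seg$v2$y - seg$v1$y
  MaxDiff <- seg$p1$y - seg$p2$y
  R <- max(seg$p1$y, seg$p2$y) - min(seg$v1$y, seg$v2$y)
  if (R <= 0) stop("degenerate stride segment: non-positive range of motion")
  data.frame(MinDiff = MinDiff, MaxDiff = MaxDiff, R = R,
             V = MinDiff / R, P = MaxDiff / R)
}

#' Metrics table for a list of segments
#' @param segments List of `stride_segment`s.
#' @return Data frame, one row per segment, with the [stride_metrics()]
#'   columns plus `t_start`, `t_end`.
#' @export
strides_table <- function(segments) {
  if (!length(segments))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      MinDiff = numeric(0), MaxDiff = numeric(0),
                      R = numeric(0), V = numeric(0), P = numeric(0)))
  do.call(rbind, lapply(segments, function(s)
    cbind(data.frame(t_start = s$t_start, t_end = s$t_end),
          stride_metrics(s))))
}
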