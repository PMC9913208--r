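# Inter-system time synchronisation and stride pairing.
#
# The two systems are triggered manually at roughly the same instant, so
# their clocks differ by a single unknown offset (recordings are short;
# no drift term). The offset is recovered by maximising the sum of the
# normalised cross-correlations of the band-pass filtered head and pelvis
# signals over both systems. Correlations are variance-normalised per body
# part so the part with the larger amplitude or longer coverage cannot
# dominate purely by scale.

#' Estimate the trigger offset between two systems
#'
#' Resamples each available body part's signal pair to a common grid by
#' linear interpolation, mean-removes and variance-normalises them (gap
#' samples contribute zero), sums the discrete normalised
#' cross-correlations of the parts and picks the lag maximising the sum;
#' the optimum is then refined by parabolic interpolation of the objective
#' around the peak.
#'
#' @param head_sc,head_mc,pelvis_sc,pelvis_mc Band-pass filtered
#'   [vd_signal()]s; either body part may be `NULL` if unavailable, but at
#'   least one part needs both systems.
#' @param search_range Maximum |shift| considered, in seconds.
#' @param grid_rate Common resampling rate in Hz (the reference system's
#'   rate by default).
#' @return A `sync_result`: list with `t_shift` (seconds to add to sc
#'   times so that they align with mc times), `objective` (summed
#'   normalised correlation at the optimum) and `search_range`.
#' @export
estimate_shift <- function(head_sc = NULL, head_mc = NULL,
                           pelvis_sc = NULL, pelvis_mc = NULL,
                           search_range = 5, grid_rate = 200) {
  parts <- list(head = list(sc = head_sc, mc = head_mc),
                pelvis = list(sc = pelvis_sc, mc = pelvis_mc))
  parts <- Filter(function(p) !is.null(p$sc) && !is.null(p$mc), parts)
  if (!length(parts))
    stop("at least one body part must be available for both systems")

  dt <- 1 / grid_rate
  span <- range(unlist(lapply(parts, function(p)
    c(range(vd_time(p$sc)), range(vd_time(p$mc))))))
  grid <- seq(span[1] - search_range, span[2] + search_range, by = dt)

  norm_on_grid <- function(v) {
    tt <- vd_time(v)
    obs <- which(!is.na(v$y))
    if (length(obs) < 2) stop("signal has fewer than 2 observed samples")
    y <- stats::approx(tt[obs], v$y[obs], grid)$y
    # interpolation is only trusted between adjacent observed samples:
    # grid points inside data gaps contribute nothing
    near <- stats::approx(tt[obs], tt[obs], grid, method = "constant",
                          rule = 2)$y
    nxt <- stats::approx(tt[obs], tt[obs], grid, method = "constant",
                         rule = 2, f = 1)$y
    y[is.na(y) | (nxt - near) > 1.5 / v$rate] <- 0
    mu <- mean(y[y != 0])
    if (is.nan(mu)) mu <- 0
    y[y != 0] <- y[y != 0] - mu
    ss <- sqrt(sum(y^2))
    if (ss == 0) stop("all-constant signal: cannot synchronise (zero variance)")
    y / ss
  }

  lags <- seq(-round(search_range / dt), round(search_range / dt))
  obj <- numeric(length(lags))
  n <- length(grid)
  for (p in parts) {
    a <- norm_on_grid(p$mc)   # reference timeline
    b <- norm_on_grid(p$sc)
    # objective(shift s): sum_t mc(t) * sc(t - s); s = lag * dt
    cc <- vapply(lags, function(l) {
      if (l >= 0) sum(a[(1 + l):n] * b[1:(n - l)])
      else sum(a[1:(n + l)] * b[(1 - l):n])
    }, 0)
    obj <- obj + cc
  }
  i <- which.max(obj)
  t_shift <- lags[i] * dt
  if (i > 1 && i < length(lags)) {
    y1 <- obj[i - 1]; y2 <- obj[i]; y3 <- obj[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den < 0) t_shift <- t_shift + 0.5 * dt * (y1 - y3) / den
  }
  if (abs(obj[i]) < 1e-12)
    stop("no overlapping support within the search range")
  structure(list(t_shift = t_shift, objective = obj[i],
                 search_range = search_range),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> t_shift = %+.4f s (objective %.3f, range +/-%g s)\n",
              x$t_shift, x$objective, x$search_range))
  invisible(x)
}

#' Pair strides observed by both systems
#'
#' Applies the estimated shift to the single-camera stride segments and
#' greedily pairs segments across systems by maximal temporal overlap
#' (fraction of the mean stride duration shared). Pairing is one-to-one;
#' pairs sharing less than `min_overlap` are discarded.
#'
#' @param mc_segments,sc_segments Lists of stride segments
#'   ([segment_strides()]) from the reference and single-camera systems.
#' @param shift A `sync_result` from [estimate_shift()] (or a numeric
#'   shift in seconds).
#' @param min_overlap Minimum overlap fraction retained.
#' @return Data frame with columns `mc`, `sc` (segment indices) and
#'   `overlap`, sorted by time; zero rows if nothing matches.
#' @export
match_strides <- function(mc_segments, sc_segments, shift,
                          min_overlap = 0.5) {
  s <- if (inherits(shift, "sync_result")) shift$t_shift else shift
  empty <- data.frame(mc = integer(0), sc = integer(0), overlap = numeric(0))
  if (!length(mc_segments) || !length(sc_segments)) return(empty)

  cand <- do.call(rbind, lapply(seq_along(mc_segments), function(i) {
    m <- mc_segments[[i]]
    do.call(rbind, lapply(seq_along(sc_segments), function(j) {
      sc <- sc_segments[[j]]
      a1 <- sc$t_start + s; a2 <- sc$t_end + s
      inter <- min(m$t_end, a2) - max(m$t_start, a1)
      dur <- ((m$t_end - m$t_start) + (a2 - a1)) / 2
      data.frame(mc = i, sc = j, overlap = inter / dur)
    }))
  }))
  cand <- cand[cand$overlap >= min_overlap, , drop = FALSE]
  cand <- cand[order(-cand$overlap), , drop = FALSE]
  used_mc <- logical(length(mc_segments))
  used_sc <- logical(length(sc_segments))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand$mc[r]; j <- cand$sc[r]
    if (!used_mc[i] && !used_sc[j]) {
      keep[r] <- TRUE
      used_mc[i] <- TRUE
      used_sc[j] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(vapply(out$mc, function(i) mc_segments[[i]]$t_start, 0)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
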