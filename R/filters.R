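# Zero-phase Butterworth filtering in second-order sections.
#
# The stride band-pass used for head/pelvis signals (10th-order prototype,
# band 0.75-2.42 x stride frequency at 200 Hz) has a very narrow normalised
# band; in direct transfer-function form its pole polynomial is numerically
# singular, so the design is kept in zero-pole form and realised as a cascade
# of biquads (the standard high-order IIR realisation).

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  p <- 1
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a Butterworth filter as second-order sections
#'
#' Designs an analog Butterworth prototype of the given order, applies the
#' band transform, maps to the digital domain with a prewarped bilinear
#' transform and pairs conjugate poles into biquad sections.
#'
#' @param order Prototype (low-pass) filter order.
#' @param rate Sampling rate in Hz.
#' @param low,high Cut-off frequencies in Hz. Band-pass filters use both;
#'   high-pass uses `low` only; low-pass uses `high` only.
#' @param type `"pass"`, `"high"` or `"low"`.
#' @return An object of class `butter_sos`: a list with `sections` (each a
#'   list with `b`, `a` length-3 numeric) and the design parameters.
#' @keywords internal
butter_sos <- function(order, rate, low = NULL, high = NULL,
                       type = c("pass", "high", "low")) {
  type <- match.arg(type)
  stopifnot(order >= 1, rate > 0)
  warp <- function(f) 2 * rate * tan(pi * f / rate)

  # analog low-pass prototype: poles on the unit left half-circle, no zeros
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  z <- complex(0)
  gain <- 1

  if (type == "pass") {
    if (is.null(low) || is.null(high) || !(0 < low && low < high && high < rate / 2))
      stop("band-pass requires 0 < low < high < rate/2")
    w1 <- warp(low); w2 <- warp(high)
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    ps <- p * bw / 2
    p <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
    z <- rep(0 + 0i, order)
    gain <- bw^order
  } else if (type == "high") {
    if (is.null(low) || !(0 < low && low < rate / 2))
      stop("high-pass requires 0 < low < rate/2")
    wc <- warp(low)
    gain <- Re(1 / prod(-p))
    p <- wc / p
    z <- rep(0 + 0i, order)
  } else {
    if (is.null(high) || !(0 < high && high < rate / 2))
      stop("low-pass requires 0 < high < rate/2")
    wc <- warp(high)
    p <- wc * p
    gain <- wc^order
  }

  # bilinear transform with gain bookkeeping
  fs2 <- 2 * rate
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  # analog zeros at infinity map to z = -1
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))

  # pair poles into conjugate biquads
  tol <- 1e-8
  pd_left <- pd
  pole_pairs <- list()
  while (length(pd_left) > 0) {
    i <- which.max(abs(pd_left))
    pi_ <- pd_left[i]; pd_left <- pd_left[-i]
    if (abs(Im(pi_)) > tol) {
      j <- which.min(abs(pd_left - Conj(pi_)))
      pole_pairs[[length(pole_pairs) + 1]] <- c(pi_, pd_left[j])
      pd_left <- pd_left[-j]
    } else {
      # real pole: pair with another real pole if available
      jr <- which(abs(Im(pd_left)) <= tol)
      if (length(jr) > 0) {
        pole_pairs[[length(pole_pairs) + 1]] <- c(pi_, pd_left[jr[1]])
        pd_left <- pd_left[-jr[1]]
      } else {
        pole_pairs[[length(pole_pairs) + 1]] <- pi_
      }
    }
  }

  # distribute zeros: band-pass gets one z=+1 and one z=-1 per section,
  # high-pass all +1, low-pass all -1; counts always match the pole count
  n_sec <- length(pole_pairs)
  zero_sets <- vector("list", n_sec)
  z_pool <- zd[order(Re(zd), decreasing = TRUE)]  # +1s first
  if (type == "pass") {
    zp <- z_pool[Re(z_pool) > 0]; zm <- z_pool[Re(z_pool) < 0]
    for (s in seq_len(n_sec)) zero_sets[[s]] <- c(zp[s], zm[s])
  } else {
    idx <- 1
    for (s in seq_len(n_sec)) {
      take <- length(pole_pairs[[s]])
      zero_sets[[s]] <- z_pool[idx:(idx + take - 1)]
      idx <- idx + take
    }
  }

  g_sec <- abs(gain)^(1 / n_sec) * ifelse(gain < 0, 1, 1)
  sections <- vector("list", n_sec)
  sgn <- sign(gain)
  for (s in seq_len(n_sec)) {
    b <- Re(poly_from_roots(zero_sets[[s]])) * g_sec
    if (s == 1) b <- b * sgn
    a <- Re(poly_from_roots(pole_pairs[[s]]))
    sections[[s]] <- list(b = b, a = a)
  }
  structure(list(sections = sections, order = order, rate = rate,
                 low = low, high = high, type = type),
            class = "butter_sos")
}

# single biquad (or first-order) IIR pass using compiled stats::filter
iir_section <- function(b, a, x) {
  n <- length(x)
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(n + nb - 1)]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase filtering with a second-order-section cascade
#'
#' Applies the cascade forward and backward (squaring the magnitude response
#' and cancelling phase). The signal is extended at both ends by odd
#' reflection before filtering so that start-up transients fall on the
#' padding, then the padding is discarded.
#'
#' @param sos A [butter_sos()] design.
#' @param x Numeric signal (no missing values).
#' @return Filtered signal, same length as `x`.
#' @keywords internal
filtfilt_sos <- function(sos, x) {
  n <- length(x)
  if (anyNA(x)) stop("filtfilt_sos: signal contains missing values")
  if (n < 8) stop("filtfilt_sos: signal too short")
  f_lo <- if (!is.null(sos$low)) sos$low else sos$high
  pad <- min(n - 1, max(24, ceiling(3 * sos$rate / f_lo)))
  head_ref <- 2 * x[1] - x[seq(pad + 1, 2)]
  tail_ref <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xx <- c(head_ref, x, tail_ref)
  for (sec in sos$sections) xx <- iir_section(sec$b, sec$a, xx)
  xx <- rev(xx)
  for (sec in sos$sections) xx <- iir_section(sec$b, sec$a, xx)
  xx <- rev(xx)
  xx[(pad + 1):(pad + n)]
}
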