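# Synthetic dual-system trot-trial generator with analytic ground truth.
#
# The latent head/pelvis signal is the two-harmonic family the analysis
# methods assume: a dominant second harmonic (twice the stride frequency,
# the symmetric movement) plus a first harmonic whose amplitude and phase
# are solved numerically so the latent's normalised extreme-value
# differences hit requested targets, all scaled to a requested range of
# motion. On top of the harmonic skeleton the generator adds the
# quasi-periodic structure of a real trot-up: per-stride timing jitter
# (stride periods vary a few percent, so the signal is not exactly
# periodic and the trigger offset between systems is identifiable),
# per-stride fluctuation of the asymmetric component, and a per-pass
# amplitude envelope (the horse speeds up and slows down between passes).
# Because the latent is known in closed form, every pipeline stage can be
# validated against exact per-stride ground truth.

#' Simulator configuration
#'
#' @param f_stride Mean stride frequency in Hz.
#' @param rom Named target range of motion in mm per part.
#' @param asym_v,asym_p Target normalised valley (V) and peak (P)
#'   differences of the latent signal (|value| <= 0.6).
#' @param n_strides Nominal stride count of the trial.
#' @param noise_sd Named per-system additive white measurement noise SD
#'   in mm.
#' @param stride_jitter SD of the per-stride fluctuation of the
#'   first-harmonic amplitude, as a fraction of the second-harmonic
#'   amplitude; emulates stride-to-stride asymmetry variability (zero
#'   gives identical truth for every stride).
#' @param period_jitter SD of the relative per-stride period fluctuation.
#' @param env_range Half-range of the per-pass amplitude envelope
#'   (fractional).
#' @param drift Amplitude in mm of a slow 0.1 Hz baseline wander.
#' @param offset Planted trigger offset in seconds: the sc clock lags the
#'   mc clock by this amount (sc time + offset = mc time).
#' @param rate_mc,rate_sc Sampling rates in Hz.
#' @param glitch_frac Fraction of sc strides corrupted by a
#'   high-frequency burst (tracking-glitch model).
#' @param hoof_amp Hoof signal amplitude in mm.
#' @param seed Integer seed; the whole trial is a deterministic function
#'   of the configuration.
#' @return A `trot_config` list.
#' @export
trot_config <- function(f_stride = 1.4, rom = c(head = 72, pelvis = 79),
                        asym_v = 0, asym_p = 0, n_strides = 28,
                        noise_sd = c(mc = 1, sc = 2), stride_jitter = 0.12,
                        period_jitter = 0.03, env_range = 0.08,
                        drift = 20, offset = 0.5, rate_mc = 200,
                        rate_sc = 60, glitch_frac = 0.05, hoof_amp = 40,
                        seed = 1) {
  stopifnot(f_stride > 0, all(rom > 0), n_strides >= 4,
            rate_mc > 0, rate_sc > 0, glitch_frac >= 0, glitch_frac <= 1)
  if (max(abs(c(asym_v, asym_p))) > 0.6)
    stop("|asymmetry targets| must be <= 0.6")
  structure(list(f_stride = f_stride, rom = rom, asym_v = asym_v,
                 asym_p = asym_p, n_strides = n_strides,
                 noise_sd = noise_sd, stride_jitter = stride_jitter,
                 period_jitter = period_jitter, env_range = env_range,
                 drift = drift, offset = offset, rate_mc = rate_mc,
                 rate_sc = rate_sc, glitch_frac = glitch_frac,
                 hoof_amp = hoof_amp, seed = as.integer(seed)),
            class = "trot_config")
}

# --- latent model ----------------------------------------------------------
# The latent is written in stride phase theta (strides completed):
#   y(t) = env(t) * [ A2 sin(4 pi theta) + a1(theta) sin(2 pi theta + phi1) ]
# theta(t) is piecewise linear with per-stride slopes 1/T_k; with no
# timing jitter theta = f t. phi2 = 0: second-harmonic peaks sit at
# phases k + 1/8 and k + 5/8, valleys at k + 3/8 and k + 7/8, and the
# first valley of stride k falls in the left-fore-high half (phase < 1/2).

latent_eval <- function(t, A2, a1_fun, phi1, theta_fun, env_fun) {
  th <- theta_fun(t)
  env_fun(t) * (A2 * sin(4 * pi * th) +
                  a1_fun(th) * sin(2 * pi * th + phi1))
}

# exact NEVd per stride via the second-harmonic extremum windows on a
# dense grid of the actual latent
latent_stride_truth <- function(strides, A2, a1_fun, phi1, theta_fun,
                                theta_inv, env_fun, dt = 1e-4,
                                window = 0.05) {
  ext <- function(tc, what) {
    g <- seq(tc - window, tc + window, by = dt)
    yv <- latent_eval(g, A2, a1_fun, phi1, theta_fun, env_fun)
    i <- if (what == "max") which.max(yv) else which.min(yv)
    c(g[i], yv[i])
  }
  do.call(rbind, lapply(strides, function(k) {
    p1 <- ext(theta_inv(k + 1 / 8), "max")
    v1 <- ext(theta_inv(k + 3 / 8), "min")
    p2 <- ext(theta_inv(k + 5 / 8), "max")
    v2 <- ext(theta_inv(k + 7 / 8), "min")
    R <- max(p1[2], p2[2]) - min(v1[2], v2[2])
    data.frame(stride = k, MinDiff = v2[2] - v1[2],
               MaxDiff = p1[2] - p2[2], R = R,
               V = (v2[2] - v1[2]) / R, P = (p1[2] - p2[2]) / R)
  }))
}

# solve (a1, phi1, scale) so an unwarped latent's NEVd equals
# (asym_v, asym_p) and its range of motion equals rom
solve_harmonics <- function(asym_v, asym_p, rom, f, dt = 1e-4) {
  ident <- function(t) f * t
  inv <- function(th) th / f
  one <- function(t) rep(1, length(t))
  unit_truth <- function(a1, phi1) {
    latent_stride_truth(0, 1, function(th) rep(a1, length(th)), phi1,
                        ident, inv, one, dt = dt)
  }
  if (asym_v == 0 && asym_p == 0) {
    a1 <- 0; phi1 <- 0
  } else {
    obj <- function(par) {
      tr <- unit_truth(par[1], par[2])
      (tr$V - asym_v)^2 + (tr$P - asym_p)^2
    }
    init <- c(sqrt(asym_v^2 + asym_p^2), atan2(asym_p, -asym_v) - pi / 4)
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    if (fit$value > 1e-8)
      stop("no valid two-harmonic solution for the requested asymmetry")
    a1 <- fit$par[1]; phi1 <- fit$par[2]
  }
  R_unit <- unit_truth(a1, phi1)$R
  scale <- rom / R_unit
  list(A2 = scale, a1 = a1 * scale, phi1 = phi1)
}

# draws everything that defines the latent (not the measurement noise):
# stride periods, per-stride first-harmonic jitter, pass envelope, drift
# phase. Called under set.seed(cfg$seed) so the oracle and the generator
# see the same latent.
sim_latent_state <- function(cfg) {
  T_ <- 1 / cfg$f_stride
  n_total <- cfg$n_strides + 3
  margin <- ceiling(8 / T_)  # strides beyond the trial at both ends
  ks <- seq(-margin, n_total + margin)
  periods <- T_ * (1 + stats::rnorm(length(ks) - 1, 0, cfg$period_jitter))
  b <- c(0, cumsum(periods))
  b <- b - b[ks == 0]  # stride 0 starts at t = 0
  # monotone cubic phase map: piecewise-linear phase would put slope
  # kinks at every stride boundary, which ring through the band-pass
  theta_fun <- stats::splinefun(b, ks, method = "hyman")
  theta_inv <- stats::splinefun(ks, b, method = "hyman")
  duration <- b[ks == n_total]

  coef <- lapply(cfg$rom, function(r)
    solve_harmonics(cfg$asym_v, cfg$asym_p, r, cfg$f_stride))
  names(coef) <- names(cfg$rom)
  a1_fun <- list()
  for (part in names(cfg$rom)) {
    co <- coef[[part]]
    eps <- stats::rnorm(length(ks) - 1, 0, cfg$stride_jitter * co$A2)
    a1_fun[[part]] <- local({
      kn <- ks[-length(ks)] + 0.5
      ka <- co$a1 + eps
      function(th) stats::approx(kn, ka, th, rule = 2)$y
    })
  }

  # per-pass amplitude envelope (pass midpoints as knots)
  pass_frac <- c(0, 0.35, 0.5, 0.85, 1)
  mids <- (pass_frac[-1] + pass_frac[-5]) / 2 * duration
  env_vals <- 1 + stats::runif(4, -cfg$env_range, cfg$env_range)
  env_fun <- local({
    m <- mids; ev <- env_vals
    function(t) stats::approx(m, ev, t, rule = 2)$y
  })
  drift_phase <- stats::runif(1, 0, 2 * pi)

  list(n_total = n_total, coef = coef, a1_fun = a1_fun,
       theta_fun = theta_fun, theta_inv = theta_inv, env_fun = env_fun,
       pass_frac = pass_frac, drift_phase = drift_phase,
       duration = duration)
}

#' Analytic ground-truth NEVd of a configuration
#'
#' Evaluates the noiseless latent signal on a dense grid (10 kHz
#' equivalent) and applies the metric definitions exactly, locating each
#' stride's two peaks and two valleys within 50 ms windows around the
#' second-harmonic extremum phases — the construction that recovers the
#' two-per-stride structure at any asymmetry. This is the brute-force
#' oracle the pipeline is validated against.
#'
#' @param cfg A [trot_config()].
#' @param dt Dense-grid step in seconds.
#' @return List with per-part data frames of per-stride `V`, `P`, `R`
#'   (`$head`, `$pelvis`), the solved harmonic coefficients (`$coef`) and
#'   the planted offset (`$true_offset`).
#' @export
oracle_nevd <- function(cfg, dt = 1e-4) {
  stopifnot(inherits(cfg, "trot_config"))
  set.seed(cfg$seed)
  state <- sim_latent_state(cfg)
  out <- list(true_offset = cfg$offset, coef = state$coef)
  for (part in names(cfg$rom)) {
    co <- state$coef[[part]]
    out[[part]] <- latent_stride_truth(
      0:(state$n_total - 1), co$A2, state$a1_fun[[part]], co$phi1,
      state$theta_fun, state$theta_inv, state$env_fun, dt = dt)
  }
  out
}

#' Generate a synthetic dual-system trot trial
#'
#' Produces a [trial_recording()] with multi-camera (mc, 200 Hz) and
#' single-camera (sc, 60 Hz) head and pelvis streams sampled from the
#' same latent trajectory plus independent measurement noise and a slow
#' baseline wander, four antiphase hoof signals on the sc stream, a
#' planted trigger offset between the system clocks, high-frequency
#' burst glitches on a fraction of sc strides, and pelvis sc data only
#' within "away" direction segments — together with exact ground truth.
#'
#' @param cfg A [trot_config()].
#' @return List with `recording` (a [trial_recording()]) and `truth`
#'   (per-part per-stride `V`, `P`, `R`; `true_offset`; `corrupted`
#'   glitch windows in world/mc time; solved coefficients).
#' @export
generate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "trot_config"))
  set.seed(cfg$seed)
  state <- sim_latent_state(cfg)
  T_ <- 1 / cfg$f_stride
  D <- state$duration
  drift <- function(t) cfg$drift * sin(2 * pi * 0.1 * t + state$drift_phase)
  noise <- function(n, sys) stats::rnorm(n, 0, noise_sd_of(cfg, sys))

  truth <- list(true_offset = cfg$offset, coef = state$coef)
  for (part in names(cfg$rom)) {
    co <- state$coef[[part]]
    truth[[part]] <- latent_stride_truth(
      0:(state$n_total - 1), co$A2, state$a1_fun[[part]], co$phi1,
      state$theta_fun, state$theta_inv, state$env_fun)
  }

  part_latent <- function(part, t) {
    co <- state$coef[[part]]
    latent_eval(t, co$A2, state$a1_fun[[part]], co$phi1,
                state$theta_fun, state$env_fun)
  }

  # mc: head + pelvis over the whole trial (world clock)
  t_mc <- seq(0, D, by = 1 / cfg$rate_mc)
  signals <- list(
    vd_signal(part_latent("head", t_mc) + drift(t_mc) +
                noise(length(t_mc), "mc"),
              cfg$rate_mc, "head", "mc"),
    vd_signal(part_latent("pelvis", t_mc) + drift(t_mc) +
                noise(length(t_mc), "mc"),
              cfg$rate_mc, "pelvis", "mc"))

  # direction passes in world time: two long "away" passes so that the
  # away-only pelvis retains enough strides relative to the head
  pf <- state$pass_frac
  passes <- data.frame(t_start = pf[-5] * D, t_end = pf[-1] * D,
                       direction = c("away", "toward", "away", "toward"))

  # sc clock: tau + offset = world time
  tau <- seq(0, D, by = 1 / cfg$rate_sc)
  w <- tau + cfg$offset

  # glitch bursts on sc strides (a quarter-stride window, world time)
  stride_ids <- 0:(state$n_total - 1)
  n_glitch <- round(cfg$glitch_frac * length(stride_ids))
  glitch <- NULL
  if (n_glitch > 0) {
    gs <- sort(sample(stride_ids, n_glitch))
    q <- sample(0:3, n_glitch, replace = TRUE)
    glitch <- data.frame(
      stride = gs,
      t_start = state$theta_inv(gs + q / 4),
      t_end = state$theta_inv(gs + (q + 1) / 4),
      freq = stats::runif(n_glitch, 15, 25))
  }
  burst <- function(t, amp) {
    b <- numeric(length(t))
    if (is.null(glitch)) return(b)
    for (r in seq_len(nrow(glitch))) {
      i <- which(t >= glitch$t_start[r] & t < glitch$t_end[r])
      if (!length(i)) next
      ph <- (t[i] - glitch$t_start[r]) / (glitch$t_end[r] - glitch$t_start[r])
      b[i] <- b[i] + amp * sin(2 * pi * glitch$freq[r] * t[i]) *
        sin(pi * ph)^2
    }
    b
  }

  sc_part <- function(part) {
    y <- part_latent(part, w) + drift(w) + noise(length(w), "sc") +
      burst(w, 3 * state$coef[[part]]$A2)
    if (part == "pelvis") {
      away <- rep(FALSE, length(w))
      for (r in which(passes$direction == "away"))
        away <- away | (w >= passes$t_start[r] & w < passes$t_end[r])
      y[!away] <- NA
    }
    vd_signal(y, cfg$rate_sc, part, "sc")
  }
  signals <- c(signals, list(sc_part("head"), sc_part("pelvis")))

  # hooves (sc): diagonal pairs move together; the left fore is high
  # during the first half of each stride phase, anchoring the side
  # convention (first valley of a stride = left-fore-high half)
  th_w <- state$theta_fun(w)
  hoof_phase <- c(hoof_lf = 0, hoof_rf = pi, hoof_lh = pi, hoof_rh = 0)
  for (kp in names(hoof_phase)) {
    y <- cfg$hoof_amp * sin(2 * pi * th_w + hoof_phase[[kp]]) +
      0.25 * cfg$hoof_amp * sin(4 * pi * th_w) + noise(length(w), "sc")
    signals <- c(signals, list(vd_signal(y, cfg$rate_sc, kp, "sc")))
  }

  directions <- passes
  directions$t_start <- directions$t_start - cfg$offset  # sc clock
  directions$t_end <- directions$t_end - cfg$offset
  rec <- trial_recording(paste0("sim", cfg$seed), signals, directions,
                         meta = list(simulated = TRUE, seed = cfg$seed))
  truth$corrupted <- glitch
  list(recording = rec, truth = truth)
}

noise_sd_of <- function(cfg, sys) {
  ns <- cfg$noise_sd
  if (is.null(names(ns))) return(ns[1])
  if (sys %in% names(ns)) ns[[sys]] else 0
}
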