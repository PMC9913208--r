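# Domain types and trajectory file I/O.
#
# All vertical displacement is carried in millimetres on a uniform sampling
# grid per signal; within-trial time is seconds from the recording start of
# the owning system (aligning the two system clocks is the synchroniser's
# job, not the file format's).

KEYPOINTS <- c("head", "pelvis", "hoof_lf", "hoof_rf", "hoof_lh", "hoof_rh")
SYSTEMS <- c("mc", "sc")

#' Vertical displacement signal
#'
#' Constructs a uniformly sampled vertical displacement signal (VDS) for one
#' keypoint observed by one system. Sample `k` (1-based) is at time
#' `t0 + (k - 1) / rate`. Missing samples (e.g. the pelvis while the horse
#' trots toward a single camera) are explicit `NA` gaps.
#'
#' @param y Numeric vector of vertical displacement in mm (`NA` = gap).
#' @param rate Sampling rate in Hz (> 0).
#' @param keypoint One of `"head"`, `"pelvis"`, `"hoof_lf"`, `"hoof_rf"`,
#'   `"hoof_lh"`, `"hoof_rh"`.
#' @param system `"mc"` (multi-camera reference) or `"sc"` (single camera).
#' @param t0 Start time in seconds of the first sample.
#' @return An object of class `vd_signal`.
#' @export
#' @examples
#' v <- vd_signal(sin(2 * pi * 1.4 * seq(0, 5, by = 1 / 60)) * 30,
#'                rate = 60, keypoint = "head", system = "sc")
#' range(vd_time(v))
vd_signal <- function(y, rate, keypoint, system, t0 = 0) {
  keypoint <- match.arg(keypoint, KEYPOINTS)
  system <- match.arg(system, SYSTEMS)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  rate <- as.numeric(rate)
  y <- as.numeric(y)
  if (length(y) < 2) stop("a vd_signal needs at least 2 samples")
  structure(list(y = y, rate = rate, keypoint = keypoint,
                 system = system, t0 = t0),
            class = "vd_signal")
}

#' Sample times of a signal
#' @param v A [vd_signal()].
#' @return Numeric vector of times in seconds.
#' @export
vd_time <- function(v) v$t0 + (seq_along(v$y) - 1) / v$rate

#' @export
print.vd_signal <- function(x, ...) {
  gaps <- sum(is.na(x$y))
  cat(sprintf("<vd_signal> %s/%s: %d samples @ %g Hz, t = [%.3f, %.3f] s%s\n",
              x$system, x$keypoint, length(x$y), x$rate,
              x$t0, max(vd_time(x)),
              if (gaps) sprintf(", %d gap samples", gaps) else ""))
  invisible(x)
}

signal_key <- function(system, keypoint) paste(system, keypoint, sep = ".")

#' Trial recording
#'
#' Container for all signals of one trot-up trial: at most one
#' [vd_signal()] per (system, keypoint), a set of direction segments
#' (time windows in which the horse moves away from or toward the single
#' camera) and free-form metadata.
#'
#' @param trial_id Character identifier.
#' @param signals List of [vd_signal()] objects.
#' @param directions Data frame with columns `t_start`, `t_end`,
#'   `direction` (`"away"`/`"toward"`); non-overlapping and time-ordered.
#' @param meta Named list of free-form metadata.
#' @return An object of class `trial_recording`; signals are keyed
#'   `"<system>.<keypoint>"`.
#' @export
trial_recording <- function(trial_id, signals, directions = NULL, meta = list()) {
  stopifnot(is.character(trial_id), length(trial_id) == 1)
  keys <- vapply(signals, function(s) signal_key(s$system, s$keypoint), "")
  if (anyDuplicated(keys))
    stop("duplicate (system, keypoint) signal: ", keys[duplicated(keys)][1])
  names(signals) <- keys
  if (is.null(directions)) {
    directions <- data.frame(t_start = numeric(0), t_end = numeric(0),
                             direction = character(0))
  } else {
    stopifnot(all(c("t_start", "t_end", "direction") %in% names(directions)))
    if (nrow(directions)) {
      if (any(directions$t_start >= directions$t_end))
        stop("direction segments must satisfy t_start < t_end")
      o <- order(directions$t_start)
      directions <- directions[o, , drop = FALSE]
      if (nrow(directions) > 1 &&
          any(directions$t_start[-1] < directions$t_end[-nrow(directions)]))
        stop("direction segments must not overlap")
      if (!all(directions$direction %in% c("away", "toward")))
        stop("direction must be 'away' or 'toward'")
    }
  }
  structure(list(trial_id = trial_id, signals = signals,
                 directions = directions, meta = meta),
            class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf("<trial_recording> '%s': %d signals, %d direction segments\n",
              x$trial_id, length(x$signals), nrow(x$directions)))
  for (s in x$signals) print(s)
  invisible(x)
}

get_signal <- function(recording, system, keypoint) {
  recording$signals[[signal_key(system, keypoint)]]
}

#' Read a trial from a trajectory CSV and its JSON sidecar
#'
#' The CSV is long format with header `time_s,keypoint,y_mm` and an optional
#' `system` column; the sidecar declares the trial id, the sampling rate per
#' system, the displacement units (must be mm) and the direction segments.
#' Timestamps are snapped to the declared rate grid when within 10% of a
#' sample period of a grid point, and rejected otherwise.
#'
#' @param csv_path Path to the trajectory CSV.
#' @param sidecar_path Path to the sidecar JSON.
#' @return A [trial_recording()].
#' @export
read_trial <- function(csv_path, sidecar_path) {
  side <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  if (is.null(side$units) || !identical(side$units, "mm"))
    stop("sidecar units must be 'mm' (got ",
         if (is.null(side$units)) "none" else side$units, ")")
  if (is.null(side$systems) || !length(side$systems))
    stop("sidecar must declare at least one system")
  rates <- lapply(side$systems, function(s) s$rate_hz)
  for (nm in names(rates)) {
    if (!nm %in% SYSTEMS) stop("unknown system in sidecar: ", nm)
    if (is.null(rates[[nm]]) || !is.numeric(rates[[nm]]) || rates[[nm]] <= 0)
      stop("missing or invalid rate_hz for system '", nm, "'")
  }

  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("time_s", "keypoint", "y_mm")
  if (!all(need %in% names(df)))
    stop("trajectory CSV must have columns time_s, keypoint, y_mm")
  if (!"system" %in% names(df)) {
    if (length(rates) != 1)
      stop("CSV has no system column but sidecar declares several systems")
    df$system <- names(rates)[1]
  }
  bad <- which(!df$keypoint %in% KEYPOINTS)
  if (length(bad))
    stop(sprintf("unknown keypoint '%s' at CSV row %d", df$keypoint[bad[1]],
                 bad[1]))
  bad <- which(!df$system %in% names(rates))
  if (length(bad))
    stop(sprintf("system '%s' at CSV row %d not declared in sidecar",
                 df$system[bad[1]], bad[1]))

  signals <- list()
  for (sys in unique(df$system)) {
    rate <- rates[[sys]]
    for (kp in unique(df$keypoint[df$system == sys])) {
      sub <- df[df$system == sys & df$keypoint == kp, , drop = FALSE]
      sub <- sub[order(sub$time_s), , drop = FALSE]
      t0 <- sub$time_s[1]
      k <- round((sub$time_s - t0) * rate)
      resid <- abs(sub$time_s - (t0 + k / rate))
      off <- which(resid > 0.1 / rate)
      if (length(off))
        stop(sprintf(
          "timestamp %.6f s (%s/%s) is off the %g Hz grid by more than 10%% of a sample period",
          sub$time_s[off[1]], sys, kp, rate))
      if (anyDuplicated(k))
        stop(sprintf("duplicate grid timestamp for %s/%s", sys, kp))
      y <- rep(NA_real_, max(k) + 1)
      y[k + 1] <- sub$y_mm
      signals[[length(signals) + 1]] <-
        vd_signal(y, rate = rate, keypoint = kp, system = sys, t0 = t0)
    }
  }

  directions <- NULL
  if (!is.null(side$directions) && length(side$directions)) {
    directions <- do.call(rbind, lapply(side$directions, function(d)
      data.frame(t_start = d$t_start, t_end = d$t_end,
                 direction = d$direction)))
  }
  trial_recording(
    trial_id = if (is.null(side$trial_id)) "trial" else side$trial_id,
    signals = signals, directions = directions,
    meta = if (is.null(side$meta)) list() else side$meta)
}

#' Write a trial to a trajectory CSV and JSON sidecar
#'
#' Inverse of [read_trial()]: gap samples are written as absent rows (never
#' NaN placeholders) and values keep full precision so that a
#' read-after-write round trip reproduces every sample exactly.
#'
#' @param recording A [trial_recording()].
#' @param csv_path,sidecar_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_trial <- function(recording, csv_path, sidecar_path) {
  rows <- lapply(recording$signals, function(s) {
    keep <- !is.na(s$y)
    data.frame(time_s = sprintf("%.10g", vd_time(s)[keep]),
               keypoint = s$keypoint,
               y_mm = sprintf("%.17g", s$y[keep]),
               system = s$system)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)

  systems <- list()
  for (s in recording$signals) systems[[s$system]] <- list(rate_hz = s$rate)
  side <- list(trial_id = recording$trial_id, systems = systems,
               units = "mm",
               directions = if (nrow(recording$directions) == 0) list() else
                 lapply(seq_len(nrow(recording$directions)), function(i)
                   as.list(recording$directions[i, ])),
               meta = recording$meta)
  jsonlite::write_json(side, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, sidecar_path))
}

#' Bundled per-trial reference tables from a dual-system validation study
#'
#' Returns the per-trial descriptive statistics bundled with the package:
#' for each of 23 horses recorded simultaneously by a marker-based
#' multi-camera system (mc) and a markerless single-camera system (sc),
#' the number of matched strides `N`, the trial-mean between-system
#' deviations `dV` and `dP` (mm, geometric scale), per-system trial means
#' and within-trial standard deviations of the MinDiff (`V`) and MaxDiff
#' (`P`) metrics, and the mc trial-mean range of motion `Rmc`.
#'
#' @param part `"head"` or `"pelvis"`.
#' @return A data frame of 23 trial rows. The column-mean row printed in
#'   the source table is not included in the rows; it is attached (for
#'   cross-checks) as `attr(x, "printed_mean")`.
#' @export
#' @examples
#' head_tab <- load_trial_tables("head")
#' sum(head_tab$N)
load_trial_tables <- function(part = c("head", "pelvis")) {
  part <- match.arg(part)
  path <- system.file("extdata", paste0(part, "_trials.csv"),
                      package = "equigait")
  if (path == "" || !file.exists(path))
    stop("bundled trial table for '", part, "' not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("horse", "N", "dV", "dP", "Vsc", "Vmc", "Psc", "Pmc",
            "sVsc", "sVmc", "sPsc", "sPmc", "Rmc")
  if (!all(need %in% names(df))) stop("trial table for '", part,
                                      "' is corrupt (columns missing)")
  mean_row <- df[df$horse == "mean", , drop = FALSE]
  trials <- df[df$horse != "mean", , drop = FALSE]
  if (nrow(trials) != 23 || nrow(mean_row) != 1)
    stop("trial table for '", part, "' is corrupt (row counts)")
  trials$N <- as.integer(trials$N)
  num <- setdiff(need, c("horse", "N"))
  for (cn in num) trials[[cn]] <- as.numeric(trials[[cn]])
  if (any(trials[, c("sVsc", "sVmc", "sPsc", "sPmc")] < 0) ||
      any(trials$Rmc <= 0))
    stop("trial table for '", part, "' is corrupt (invalid values)")
  rownames(trials) <- NULL
  attr(trials, "printed_mean") <- mean_row
  trials
}

#' Write an agreement report to JSON
#'
#' Serialises an [agreement_report()] (per-stride deviations, per-trial
#' summary rows and dataset aggregates) to a JSON document that
#' [read_report()] restores losslessly.
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(path)
}

#' Read an agreement report from JSON
#' @param path Path written by [write_report()].
#' @return An `agreement_report`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (part in names(x$parts)) {
    p <- x$parts[[part]]
    for (nm in c("strides", "trials")) {
      if (is.null(p[[nm]]) || (is.list(p[[nm]]) && !length(p[[nm]]))) {
        x$parts[[part]][[nm]] <- empty_report_df(nm)
      } else {
        x$parts[[part]][[nm]] <- as.data.frame(p[[nm]])
      }
    }
  }
  structure(x, class = "agreement_report")
}

empty_report_df <- function(which) {
  if (which == "strides")
    data.frame(trial_id = character(0), stride = integer(0),
               dV = numeric(0), dP = numeric(0), Vsc = numeric(0),
               Vmc = numeric(0), Psc = numeric(0), Pmc = numeric(0))
  else
    data.frame(trial_id = character(0), N = integer(0), dV = numeric(0),
               dP = numeric(0), Vsc = numeric(0), Vmc = numeric(0),
               Psc = numeric(0), Pmc = numeric(0), sVsc = numeric(0),
               sVmc = numeric(0), sPsc = numeric(0), sPmc = numeric(0),
               Rmc = numeric(0))
}
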