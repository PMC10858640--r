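# Daily composite score: seven trailing-window component statistics summed
# into the HF Score, a transmission-rate gate, and the alert hysteresis
# state machine.

#' Component names of the composite score
#'
#' The seven dynamic components, in the order used throughout the package:
#' 24 h mean heart rate trend (`hr24`), heart-rate-variability decrease
#' (`hrv`), nocturnal heart-rate instability (`night_hr`), thoracic-impedance
#' decrease (`ti`), physical-activity decrease (`activity`), atrial
#' high-rate-episode burden (`ahre`) and premature-ventricular-contraction
#' trend (`pvc`).
#'
#' @return Character vector of length 7.
#' @export
score_components <- function() {
  c("hr24", "hrv", "night_hr", "ti", "activity", "ahre", "pvc")
}

#' Scoring-engine configuration
#'
#' Parameters of the daily scoring engine: per-component weights (the maximum
#' attainable contribution of each component, in score points), the alert
#' thresholds, and the windowing/gating rules.
#'
#' @param weights Named numeric vector of per-component maximum contributions
#'   (score points). Names must be [score_components()]. The defaults
#'   (20, 20, 15, 15, 10, 10, 10; total 100) put the most weight on the
#'   heart-rate and impedance channels, consistent with their dominant share
#'   of the composite in decompensating patients.
#' @param nominal_threshold Alert trigger level in score points (default 45).
#' @param recovery_offset The recovery threshold is
#'   `nominal_threshold - recovery_offset` (default offset 10); an active
#'   alert clears only below the recovery threshold (hysteresis).
#' @param stable_exceed_days Number of consecutive valid days the score must
#'   exceed the nominal threshold before an alert starts (default 2).
#' @param window_days Length of the trailing window feeding the component
#'   statistics, in days (default 84, i.e. 12 weeks).
#' @param min_window_days Minimum number of measured days in the window for
#'   the day's score to be considered valid (default 10).
#' @param min_transmission_rate Minimum fraction of transmitting days within
#'   the trailing transmission horizon (default 0.55).
#' @param transmission_horizon_days Horizon of the transmission-rate gate in
#'   days (default 90).
#' @param run_in_days Post-implant stabilization period during which no score
#'   is issued (default 30 days).
#' @param night_hr_ref_sd Reference dispersion (bpm) against which the
#'   nocturnal heart-rate standard deviation is normalized; the instability
#'   statistic is `min(1, sd / night_hr_ref_sd)`. Default 5 bpm.
#' @param night_hr_span_days Trailing span (days) over which the nocturnal
#'   dispersion is computed (default 28).
#' @param ahre_saturation_pct Atrial burden (percent of 24 h) at which the
#'   burden component saturates at its full weight (default 50).
#' @param ahre_exclusion_pct Days with atrial burden above this percentage are
#'   excluded from the heart-rate-variability statistic (default 20), since
#'   HRV is only meaningful outside atrial high-rate episodes.
#'
#' @return An object of class `engine_config` (a named list).
#' @export
engine_config <- function(weights = c(hr24 = 20, hrv = 20, night_hr = 15,
                                      ti = 15, activity = 10, ahre = 10,
                                      pvc = 10),
                          nominal_threshold = 45,
                          recovery_offset = 10,
                          stable_exceed_days = 2,
                          window_days = 84,
                          min_window_days = 10,
                          min_transmission_rate = 0.55,
                          transmission_horizon_days = 90,
                          run_in_days = 30,
                          night_hr_ref_sd = 5,
                          night_hr_span_days = 28,
                          ahre_saturation_pct = 50,
                          ahre_exclusion_pct = 20) {
  comp <- score_components()
  if (is.null(names(weights)) || !setequal(names(weights), comp)) {
    stop("'weights' must be named with: ", paste(comp, collapse = ", "))
  }
  weights <- weights[comp]
  if (any(weights < 0)) stop("component weights must be >= 0")
  if (nominal_threshold <= recovery_offset) {
    stop("nominal_threshold must exceed recovery_offset")
  }
  if (window_days < 7) stop("window_days must be >= 7")
  if (stable_exceed_days < 1) stop("stable_exceed_days must be >= 1")
  if (min_transmission_rate < 0 || min_transmission_rate > 1) {
    stop("min_transmission_rate must be in [0, 1]")
  }
  structure(list(weights = weights,
                 nominal_threshold = nominal_threshold,
                 recovery_offset = recovery_offset,
                 stable_exceed_days = stable_exceed_days,
                 window_days = window_days,
                 min_window_days = min_window_days,
                 min_transmission_rate = min_transmission_rate,
                 transmission_horizon_days = transmission_horizon_days,
                 run_in_days = run_in_days,
                 night_hr_ref_sd = night_hr_ref_sd,
                 night_hr_span_days = night_hr_span_days,
                 ahre_saturation_pct = ahre_saturation_pct,
                 ahre_exclusion_pct = ahre_exclusion_pct),
            class = "engine_config")
}

#' Normalized monotone-trend statistic
#'
#' A Mann-Kendall-type concordance statistic rescaled to `[0, 1]`:
#' the signed pair concordance `S = sum over i < j of sign(x_j - x_i)` divided
#' by the number of pairs, with the negative part clipped. `mk_trend(x, "inc")`
#' is 1 for a strictly increasing series, 0 for constant or non-increasing
#' ones; `"dec"` mirrors it. The statistic is invariant to adding a constant
#' and to strictly monotone rescaling of the values.
#'
#' @param x Numeric series (chronological); `NA`s are dropped.
#' @param direction `"inc"` or `"dec"`.
#' @return A number in `[0, 1]`; 0 when fewer than 2 finite values remain.
#' @export
mk_trend <- function(x, direction = c("inc", "dec")) {
  direction <- match.arg(direction)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(0)
  d <- sign(outer(x, x, "-"))
  s <- sum(d[lower.tri(d)])  # sign(x_j - x_i) for j > i
  tau <- s / (n * (n - 1) / 2)
  if (direction == "dec") tau <- -tau
  max(0, tau)
}

#' Compute the seven component scores from one trailing window
#'
#' Applies the per-component statistics to a trailing window of daily
#' telemetry (at most `window_days` rows): monotone-increase statistics for
#' 24 h heart rate and PVC rate, monotone-decrease statistics for HRV,
#' thoracic impedance and activity, a dispersion statistic for nocturnal
#' heart rate and a saturating level statistic for atrial burden. Each
#' statistic lies in `[0, 1]` and is multiplied by the component's weight.
#' HRV days with atrial burden above `ahre_exclusion_pct` are excluded from
#' the HRV statistic. Only transmitted days carry measurements.
#'
#' @param window A data frame of daily telemetry rows (columns `day`, `hr24`,
#'   `night_hr`, `hrv`, `ahre_pct`, `pvc_per_h`, `activity`, `impedance`,
#'   `transmitted`), chronological, spanning at most `window_days` days.
#' @param config An [engine_config()].
#' @return One-row data frame with the seven component columns, `n_days`
#'   (measured days used) and `valid` (`n_days >= min_window_days`).
#' @export
compute_components <- function(window, config = engine_config()) {
  if (nrow(window) > 1 && is.unsorted(window$day)) {
    stop("window must be in chronological order")
  }
  if (nrow(window) > 0 && diff(range(window$day)) >= config$window_days) {
    stop("window spans more than window_days days")
  }
  w <- window[as.logical(window$transmitted), , drop = FALSE]
  n <- nrow(w)
  wt <- config$weights
  out <- as.list(stats::setNames(numeric(7), score_components()))
  if (n >= config$min_window_days) {
    out$hr24 <- wt[["hr24"]] * mk_trend(w$hr24, "inc")
    out$pvc <- wt[["pvc"]] * mk_trend(w$pvc_per_h, "inc")
    out$ti <- wt[["ti"]] * mk_trend(w$impedance, "dec")
    out$activity <- wt[["activity"]] * mk_trend(w$activity, "dec")
    hrv_ok <- !is.na(w$ahre_pct) & w$ahre_pct <= config$ahre_exclusion_pct
    out$hrv <- wt[["hrv"]] * mk_trend(w$hrv[hrv_ok], "dec")
    last_day <- max(w$day)
    nh <- w$night_hr[w$day > last_day - config$night_hr_span_days]
    nh <- nh[!is.na(nh)]
    disp <- if (length(nh) >= 2) stats::sd(nh) / config$night_hr_ref_sd else 0
    out$night_hr <- wt[["night_hr"]] * min(1, disp)
    burden <- mean(w$ahre_pct, na.rm = TRUE)
    if (is.nan(burden)) burden <- 0
    out$ahre <- wt[["ahre"]] * min(1, burden / config$ahre_saturation_pct)
  }
  data.frame(out, n_days = n, valid = n >= config$min_window_days)
}

#' Compose the daily score from its components
#'
#' The HF Score is the exact sum of the seven non-negative component scores;
#' the HF index is the score divided by 10.
#'
#' @param components Named numeric vector (or one-row data frame) holding the
#'   seven components named as in [score_components()].
#' @return A list with `score`, `index` and `components`.
#' @export
compose_score <- function(components) {
  if (is.data.frame(components)) components <- unlist(components[1, score_components()])
  comp <- components[score_components()]
  if (anyNA(comp)) stop("all seven components are required")
  if (any(comp < 0)) stop("components must be non-negative")
  score <- sum(comp)
  list(score = score, index = score / 10, components = comp)
}

#' Trailing transmission rate
#'
#' Fraction of days with a data transmission within the trailing horizon
#' (default 90 days) ending at `day`. For series younger than the horizon the
#' denominator is the series age, so a fully transmitting young series scores
#' 1 rather than being penalized for its short history.
#'
#' @param transmitted Logical (or 0/1) vector of daily transmission flags.
#' @param days Integer day indices corresponding to `transmitted`.
#' @param day The day at which the rate is evaluated (inclusive).
#' @param horizon Horizon length in days (default 90).
#' @return A fraction in `[0, 1]`.
#' @export
transmission_rate <- function(transmitted, days, day, horizon = 90) {
  if (length(transmitted) == 0) stop("empty transmission series")
  if (length(transmitted) != length(days)) stop("flags and days differ in length")
  start <- max(min(days), day - horizon + 1)
  denom <- day - start + 1
  if (denom <= 0) stop("day precedes the series start")
  keep <- days >= start & days <= day
  sum(as.logical(transmitted[keep])) / denom
}

#' Alert hysteresis state machine
#'
#' Walks a chronological daily score series and emits alert episodes. An
#' episode starts on the first day of `stable_exceed_days` consecutive valid
#' days with score strictly above the nominal threshold while not in alert;
#' it ends on the first subsequent day with score strictly below the recovery
#' threshold (`nominal_threshold - recovery_offset`). Missing or invalid days
#' pause the consecutive-day counter without resetting it, and never end an
#' episode. Episodes are non-overlapping and ordered.
#'
#' @param scores Data frame with columns `day`, `score` and optionally
#'   `valid` (defaults to all valid), sorted by `day`.
#' @param config An [engine_config()].
#' @return Data frame with columns `start_day`, `end_day` (`NA` while
#'   ongoing) and `threshold_at_start`.
#' @export
update_alert_state <- function(scores, config = engine_config()) {
  if (nrow(scores) > 1 && is.unsorted(scores$day)) {
    stop("scores must be in chronological order")
  }
  valid <- if ("valid" %in% names(scores)) as.logical(scores$valid) else
    rep(TRUE, nrow(scores))
  thr <- config$nominal_threshold
  rec <- thr - config$recovery_offset
  in_alert <- FALSE
  run <- 0L
  run_start <- NA_integer_
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nrow(scores))) {
    if (!valid[i] || is.na(scores$score[i])) next  # gaps pause the counter
    s <- scores$score[i]
    d <- scores$day[i]
    if (in_alert) {
      if (s < rec) {
        ends[length(starts)] <- d
        in_alert <- FALSE
        run <- 0L
      }
    } else {
      if (s > thr) {
        if (run == 0L) run_start <- d
        run <- run + 1L
        if (run >= config$stable_exceed_days) {
          starts <- c(starts, run_start)
          ends <- c(ends, NA_integer_)
          in_alert <- TRUE
          run <- 0L
        }
      } else {
        run <- 0L
      }
    }
  }
  data.frame(start_day = starts, end_day = ends,
             threshold_at_start = rep(thr, length(starts)))
}

#' Score a daily telemetry table
#'
#' Computes the daily component scores and composite score for every patient
#' and every day from the end of the post-implant run-in onward, using the
#' trailing `window_days` window of transmitted measurements, and flags each
#' day as valid when both the minimum measured-day rule and the trailing
#' transmission-rate gate are satisfied.
#'
#' @param telemetry Data frame as written by [simulate_telemetry()] (columns
#'   `patient_id`, `day`, the seven measurement columns, `transmitted`).
#' @param config An [engine_config()].
#' @return Data frame with one row per patient-day from `run_in_days` onward:
#'   component columns, `score`, `index`, `n_days`, `transmission_rate`,
#'   `valid`, `transmitted`.
#' @export
score_telemetry <- function(telemetry, config = engine_config()) {
  split_tel <- split(telemetry, telemetry$patient_id)
  res <- lapply(split_tel, function(tel) {
    tel <- tel[order(tel$day), ]
    days <- tel$day[tel$day >= config$run_in_days]
    if (length(days) == 0) return(NULL)
    rows <- lapply(days, function(d) {
      win <- tel[tel$day > d - config$window_days & tel$day <= d, ,
                 drop = FALSE]
      comp <- compute_components(win, config)
      tr <- transmission_rate(tel$transmitted, tel$day, d,
                              config$transmission_horizon_days)
      comp$score <- sum(unlist(comp[1, score_components()]))
      comp$index <- comp$score / 10
      comp$transmission_rate <- tr
      comp$valid <- comp$valid && tr >= config$min_transmission_rate
      comp
    })
    out <- do.call(rbind, rows)
    out$patient_id <- tel$patient_id[1]
    out$day <- days
    out$transmitted <- tel$transmitted[match(days, tel$day)]
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("patient_id", "day", score_components(), "score", "index",
          "n_days", "transmission_rate", "valid", "transmitted")]
}
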