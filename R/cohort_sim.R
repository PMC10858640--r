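# Seeded synthetic cohorts: patients, covariates, hospitalization events,
# daily component-score series and raw telemetry with the longitudinal
# structure the trend analysis assumes.

#' Cohort-generator configuration
#'
#' Defaults emulate the development cohort of the score: 2050 patients of
#' whom 259 have a total of 369 worsening-HF hospitalizations, per-trial
#' allocation matching the reported per-trial counts, and covariate
#' prevalences matching the reported baseline table.
#'
#' @param n_event_patients Number of patients with at least one
#'   hospitalization (default 259).
#' @param n_control_patients Number of patients without hospitalizations
#'   (default 1791).
#' @param n_events_total If not `NULL` (default 369), events are allocated so
#'   the cohort has exactly this many hospitalizations, each event patient
#'   receiving 1 to 3; if `NULL`, per-patient counts are drawn independently
#'   from `events_per_patient_probs`.
#' @param events_per_patient_probs Probabilities over 1, 2 and 3 events per
#'   event patient, used when `n_events_total` is `NULL`.
#' @param follow_up_days Length-2 integer range of per-patient follow-up
#'   (days post-implant; default 240 to 720).
#' @param transmission_probability Daily probability of a remote
#'   transmission (default 0.9, the typical compliance of these systems).
#' @param min_event_day Earliest admission day post-implant (default 121:
#'   30-day run-in plus a full 91-day analysis window).
#' @param min_event_gap Minimum days between a patient's consecutive
#'   admissions (default 91, so windows are never truncated).
#' @param allow_truncated_windows If `TRUE`, lowers `min_event_day` to 45 and
#'   `min_event_gap` to 30 so early and closely repeated events exercise the
#'   window-truncation rules (default `FALSE`).
#' @param covariate_prevalences List with elements `event` and `control`,
#'   each a named vector of prevalences for `male`, `nyha3`, `af_history`,
#'   `renal`, `ischaemic`, `crtd`.
#' @param trial_allocation Data frame as [reference_trial_counts()] giving
#'   the exact per-trial allocation of patients, event patients and events,
#'   or `NULL` to label all patients with a single synthetic trial.
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical cohorts.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_event_patients = 259,
                          n_control_patients = 1791,
                          n_events_total = 369,
                          events_per_patient_probs = c(0.70, 0.22, 0.08),
                          follow_up_days = c(240L, 720L),
                          transmission_probability = 0.9,
                          min_event_day = 121L,
                          min_event_gap = 91L,
                          allow_truncated_windows = FALSE,
                          covariate_prevalences = default_covariate_prevalences(),
                          trial_allocation = reference_trial_counts(),
                          seed = 1L) {
  if (n_event_patients < 0 || n_control_patients < 0) {
    stop("patient counts must be non-negative")
  }
  if (n_event_patients + n_control_patients <= 0) {
    stop("cohort must contain at least one patient")
  }
  if (transmission_probability < 0 || transmission_probability > 1) {
    stop("transmission_probability must be in [0, 1]")
  }
  probs <- events_per_patient_probs / sum(events_per_patient_probs)
  if (any(probs < 0)) stop("event-count probabilities must be non-negative")
  pv <- unlist(covariate_prevalences)
  if (any(pv < 0 | pv > 1)) stop("covariate prevalences must be in [0, 1]")
  if (allow_truncated_windows) {
    min_event_day <- 45L
    min_event_gap <- 30L
  }
  if (!is.null(n_events_total)) {
    if (n_event_patients > 0 &&
        (n_events_total < n_event_patients ||
         n_events_total > 3 * n_event_patients)) {
      stop("n_events_total must lie in [n_event_patients, 3*n_event_patients]")
    }
  }
  if (!is.null(trial_allocation)) {
    ok <- sum(trial_allocation$n_patients) ==
      n_event_patients + n_control_patients &&
      sum(trial_allocation$n_event_patients) == n_event_patients &&
      (is.null(n_events_total) ||
         sum(trial_allocation$n_events) == n_events_total)
    if (!ok) trial_allocation <- NULL  # totals differ: fall back to one label
  }
  structure(list(n_event_patients = as.integer(n_event_patients),
                 n_control_patients = as.integer(n_control_patients),
                 n_events_total = if (is.null(n_events_total)) NULL else
                   as.integer(n_events_total),
                 events_per_patient_probs = probs,
                 follow_up_days = as.integer(follow_up_days),
                 transmission_probability = transmission_probability,
                 min_event_day = as.integer(min_event_day),
                 min_event_gap = as.integer(min_event_gap),
                 allow_truncated_windows = allow_truncated_windows,
                 covariate_prevalences = covariate_prevalences,
                 trial_allocation = trial_allocation,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Default covariate prevalences by group
#'
#' Prevalences of the dichotomized baseline characteristics in the
#' hospitalized (`event`) and non-hospitalized (`control`) groups of the
#' development cohort.
#'
#' @return List with named vectors `event` and `control`.
#' @export
default_covariate_prevalences <- function() {
  list(event = c(male = 0.792, nyha3 = 0.637, af_history = 0.454,
                 renal = 0.335, ischaemic = 0.544, crtd = 0.707),
       control = c(male = 0.764, nyha3 = 0.538, af_history = 0.193,
                   renal = 0.183, ischaemic = 0.482, crtd = 0.765))
}

# Deterministic per-patient seed split keyed on the patient identifier, so
# any patient subset reproduces its series independently of cohort size.
patient_seed <- function(seed, patient_id) {
  h <- 0
  for (v in utf8ToInt(as.character(patient_id))) {
    h <- (h * 31 + v) %% 2147483647
  }
  ((abs(as.numeric(seed)) %% 100000) * 20011 + h * 7) %% 2147483647
}

#' Generate a synthetic patient cohort with hospitalization events
#'
#' Draws patients (with covariates and trial labels), follow-up spans and
#' worsening-HF admission days. Implant day is day 0 for every patient; all
#' day indices count from implant. Generated patients satisfy the
#' eligibility criteria of the analysis (LVEF at most 35, NYHA II/III,
#' active remote monitoring), so the cascade passes them through.
#'
#' @param config A [cohort_config()].
#' @return List with data frames `patients` (one row per patient) and
#'   `events` (columns `patient_id`, `event_id`, `admission_day`,
#'   `adjudicated`).
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ne <- config$n_event_patients
  nc <- config$n_control_patients
  n <- ne + nc
  ids <- sprintf("P%04d", seq_len(n))
  group <- rep(c("event", "control"), c(ne, nc))

  # trial labels; exact per-trial allocation of event/control patients
  trial <- rep("SYNTHETIC", n)
  if (!is.null(config$trial_allocation)) {
    ta <- config$trial_allocation
    trial[group == "event"] <- rep(ta$trial, ta$n_event_patients)
    trial[group == "control"] <- rep(ta$trial,
                                     ta$n_patients - ta$n_event_patients)
  }

  # events per event patient
  k <- integer(0)
  if (ne > 0) {
    if (!is.null(config$n_events_total)) {
      extras <- config$n_events_total - ne
      k <- rep(1L, ne)
      if (!is.null(config$trial_allocation)) {
        # allocate extra events within each trial so per-trial totals match
        ta <- config$trial_allocation
        offs <- c(0L, cumsum(ta$n_event_patients))
        for (j in seq_len(nrow(ta))) {
          ex <- ta$n_events[j] - ta$n_event_patients[j]
          if (ex > 0) {
            slots <- rep(offs[j] + seq_len(ta$n_event_patients[j]), 2L)
            pick <- sample(slots, ex)
            k <- k + tabulate(pick, nbins = ne)
          }
        }
      } else if (extras > 0) {
        pick <- sample(rep(seq_len(ne), 2L), extras)
        k <- k + tabulate(pick, nbins = ne)
      }
    } else {
      k <- sample(1:3, ne, replace = TRUE,
                  prob = config$events_per_patient_probs)
    }
  }

  # follow-up: long enough for each patient's events plus a margin
  lo <- config$follow_up_days[1]
  hi <- config$follow_up_days[2]
  need <- rep(lo, n)
  if (ne > 0) {
    need[group == "event"] <-
      pmax(lo, config$min_event_day + (k - 1L) * config$min_event_gap + 14L)
  }
  follow_up_end <- need + sapply(pmax(hi - need, 0L) + 1L,
                                 function(m) sample.int(m, 1L) - 1L)

  # covariates
  pv <- config$covariate_prevalences
  draw <- function(nm) {
    p <- ifelse(group == "event", pv$event[[nm]], pv$control[[nm]])
    stats::rbinom(n, 1, p) == 1
  }
  male <- draw("male")
  nyha <- ifelse(draw("nyha3"), "III", "II")
  af <- draw("af_history")
  renal <- draw("renal")
  isch <- draw("ischaemic")
  crtd <- draw("crtd")
  age <- pmin(95, pmax(30, round(stats::rnorm(n, 67.5, 10))))
  bmi <- round(pmin(48, pmax(16, stats::rnorm(n, 27.5, 4.5))), 1)
  lvef <- sample(15:35, n, replace = TRUE)

  patients <- data.frame(
    patient_id = ids, group = group, trial = trial,
    implant_day = 0L, follow_up_end = follow_up_end,
    age = age, sex = ifelse(male, "male", "female"), bmi = bmi,
    nyha = nyha, lvef = lvef, af_history = af, renal_insufficiency = renal,
    ischaemic = isch, device = ifelse(crtd, "CRT-D", "ICD"),
    device_ok = TRUE, longstanding_af = FALSE, hm_data_ok = TRUE,
    has_whfh = group == "event",
    stringsAsFactors = FALSE
  )

  # admission days: sequential draws respecting the minimum gap
  events <- data.frame(patient_id = character(0), event_id = character(0),
                       admission_day = integer(0), adjudicated = logical(0))
  if (ne > 0) {
    ev_pid <- rep(ids[seq_len(ne)], k)
    ev_day <- integer(sum(k))
    pos <- 1L
    for (i in seq_len(ne)) {
      fu <- follow_up_end[i]
      prev <- config$min_event_day - config$min_event_gap
      for (j in seq_len(k[i])) {
        lo_d <- max(config$min_event_day, prev + config$min_event_gap)
        hi_d <- fu - (k[i] - j) * config$min_event_gap
        d <- lo_d + sample.int(max(hi_d - lo_d, 0L) + 1L, 1L) - 1L
        ev_day[pos] <- d
        prev <- d
        pos <- pos + 1L
      }
    }
    events <- data.frame(
      patient_id = ev_pid,
      event_id = paste0(ev_pid, "_e", unlist(lapply(k, seq_len))),
      admission_day = ev_day, adjudicated = TRUE,
      stringsAsFactors = FALSE
    )
  }
  list(patients = patients, events = events)
}

#' Trajectory specification for the component-score simulator
#'
#' Per-component expected weekly means at Week -12 and Week 0 for each group,
#' the variance decomposition (patient-level and anchor-level random
#' intercepts plus daily residual noise, all in score points), a trend shape
#' per component, and optional residual autocorrelation.
#'
#' The defaults are calibrated to the development cohort: the means are the
#' reported endpoint values ([reference_component_means()]) and the three
#' standard deviations split each component's reported cross-sectional SD
#' `s` as patient 0.6 s, anchor 0.3 s and daily residual `sqrt(3.85) s`, so
#' the variance of a 7-day weekly mean is approximately `s^2`.
#'
#' @param means 7 x 4 matrix as [reference_component_means()].
#' @param patient_sd,anchor_sd,residual_sd Numeric length-7 (or scalar)
#'   standard deviations in score points; `residual_sd` is per day.
#' @param shape Character length-7, `"linear"` (default) or `"plateau"`; a
#'   plateau component reaches its Week 0 mean at Week -6 and stays there.
#' @param ar1 Residual lag-1 autocorrelation within patient, in [0, 1)
#'   (default 0).
#' @return An object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(means = reference_component_means(),
                            patient_sd = 0.6 * reference_component_sds()[, "event_w12"],
                            anchor_sd = 0.3 * reference_component_sds()[, "event_w12"],
                            residual_sd = sqrt(3.85) * reference_component_sds()[, "event_w12"],
                            shape = rep("linear", 7),
                            ar1 = 0) {
  comp <- score_components()
  if (any(means < 0)) stop("trajectory means must be non-negative")
  expand <- function(x, nm) {
    x <- rep_len(x, 7)
    if (any(x < 0)) stop(nm, " must be non-negative")
    stats::setNames(x, comp)
  }
  if (!all(shape %in% c("linear", "plateau"))) {
    stop("shape must be 'linear' or 'plateau'")
  }
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must be in [0, 1)")
  structure(list(means = means,
                 patient_sd = expand(patient_sd, "patient_sd"),
                 anchor_sd = expand(anchor_sd, "anchor_sd"),
                 residual_sd = expand(residual_sd, "residual_sd"),
                 shape = stats::setNames(rep_len(shape, 7), comp),
                 ar1 = ar1),
            class = "trajectory_spec")
}

# Expected daily mean by day-offset before the anchor (offset 0 = anchor
# day). The ramp is anchored at the week-bin midpoints (offsets 3 and 87),
# so the Week 0 and Week -12 bin averages equal mu0 and mu12 exactly.
# Offsets beyond 90 hold the Week -12 baseline. Returns offsets 0..90 plus a
# final baseline entry.
daily_mean_profile <- function(mu12, mu0, shape) {
  off <- 0:90
  if (shape == "plateau") {
    mu <- ifelse(off <= 45, mu0, mu0 + (mu12 - mu0) * (off - 45) / 42)
  } else {
    mu <- mu0 + (mu12 - mu0) * (off - 3) / 84
  }
  c(pmax(mu, 0), mu12)
}

# Latent Gaussian mean whose zero-floored expectation equals `target`:
# solves sigma * (z*pnorm(z) + dnorm(z)) = target for z. Keeps expected
# component values on target despite the non-negativity floor.
latent_floor_mean <- function(target, sigma) {
  if (sigma <= 0) return(target)
  ut <- unique(target)
  g <- function(z) z * stats::pnorm(z) + stats::dnorm(z)
  lat <- vapply(ut, function(tt) {
    r <- tt / sigma
    if (r > 8) return(tt)            # floor never binds in practice
    if (r < 1e-10) return(-15 * sigma)
    sigma * stats::uniroot(function(z) g(z) - r, c(-15, r + 1),
                           tol = 1e-10)$root
  }, numeric(1))
  lat[match(target, ut)]
}

#' Simulate daily component-score series for a cohort
#'
#' For event patients, each component's expected value follows its trend
#' shape from the Week -12 mean to the Week 0 mean over the 91 days before
#' each admission (days outside any pre-event window sit at the Week -12
#' baseline); for control patients the window precedes the end of follow-up.
#' Patient-level and anchor-level random intercepts and daily residual noise
#' are added, and values are floored at zero. The floor is moment-matched:
#' the latent Gaussian mean is adjusted so the floored expectation equals
#' the target mean exactly, keeping weekly bin means on their configured
#' values. Each day carries a transmission flag.
#'
#' @param patients,events As returned by [make_cohort()].
#' @param trajectory A [trajectory_spec()].
#' @param transmission_probability Daily transmission probability.
#' @param seed Integer seed (split deterministically per patient).
#' @return Data frame with one row per patient-day: `patient_id`, `day`,
#'   `group`, the seven component columns, `score`, `index`, `valid`,
#'   `transmitted`.
#' @export
simulate_component_scores <- function(patients, events,
                                      trajectory = trajectory_spec(),
                                      transmission_probability = 0.9,
                                      seed = 1L) {
  stopifnot(inherits(trajectory, "trajectory_spec"))
  comp <- score_components()
  mu <- trajectory$means
  sig_tot <- sqrt(trajectory$patient_sd^2 + trajectory$anchor_sd^2 +
                    trajectory$residual_sd^2)
  # latent daily-mean profiles (offset 0..90 + baseline row 92)
  lat <- list(event = matrix(0, 92, 7, dimnames = list(NULL, comp)),
              control = matrix(0, 92, 7, dimnames = list(NULL, comp)))
  for (j in seq_len(7)) {
    pe <- daily_mean_profile(mu[j, "event_w12"], mu[j, "event_w0"],
                             trajectory$shape[j])
    pc <- daily_mean_profile(mu[j, "control_w12"], mu[j, "control_w0"],
                             trajectory$shape[j])
    lat$event[, j] <- latent_floor_mean(pe, sig_tot[j])
    lat$control[, j] <- latent_floor_mean(pc, sig_tot[j])
  }

  ev_by_pat <- split(events$admission_day, events$patient_id)
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    grp <- patients$group[i]
    fu <- patients$follow_up_end[i]
    days <- 0:fu
    nd <- length(days)
    anchors <- if (grp == "event") sort(ev_by_pat[[pid]]) else fu
    if (is.null(anchors)) anchors <- integer(0)
    # nearest subsequent anchor; segment 0 = baseline
    jj <- findInterval(days - 0.5, anchors) + 1L
    in_win <- jj <= length(anchors)
    offset <- rep(92L, nd)          # baseline profile row
    seg <- rep(0L, nd)
    if (any(in_win)) {
      o <- anchors[jj[in_win]] - days[in_win]
      use <- o <= 90
      offset[in_win][use] <- o[use] + 1L
      seg[in_win][use] <- jj[in_win][use]
    }
    set.seed(patient_seed(seed, pid))
    b_p <- stats::rnorm(7) * trajectory$patient_sd
    n_seg <- length(anchors)
    b_a <- matrix(stats::rnorm(7 * (n_seg + 1L)), n_seg + 1L, 7,
                  byrow = TRUE) * rep(trajectory$anchor_sd,
                                      each = n_seg + 1L)
    eps <- matrix(stats::rnorm(nd * 7), nd, 7)
    if (trajectory$ar1 > 0) {
      rho <- trajectory$ar1
      eps <- apply(eps, 2, function(z) {
        as.numeric(stats::filter(z * sqrt(1 - rho^2), rho,
                                 method = "recursive", init = z[1]))
      })
    }
    eps <- eps * rep(trajectory$residual_sd, each = nd)
    vals <- lat[[grp]][offset, , drop = FALSE] +
      rep(b_p, each = nd) + b_a[seg + 1L, , drop = FALSE] + eps
    vals <- pmax(vals, 0)
    transmitted <- stats::rbinom(nd, 1, transmission_probability)
    out[[i]] <- cbind(day = days, vals, transmitted = transmitted)
  }
  m <- do.call(rbind, out)
  res <- data.frame(
    patient_id = rep(patients$patient_id, patients$follow_up_end + 1L),
    day = as.integer(m[, "day"]),
    group = rep(patients$group, patients$follow_up_end + 1L),
    m[, comp, drop = FALSE],
    stringsAsFactors = FALSE
  )
  res$score <- rowSums(m[, comp, drop = FALSE])
  res$index <- res$score / 10
  res$valid <- TRUE
  res$transmitted <- as.integer(m[, "transmitted"])
  res
}

#' Telemetry-generator profile
#'
#' Baselines, day-to-day noise, between-patient variation and pre-event
#' drift of the raw physiologic channels. The default drift rates (applied
#' over the `drift_days` before each admission) are calibrated so that the
#' scoring engine's component statistics on event windows at Week -12
#' reproduce the reported component contribution structure of the composite
#' (roughly 32/22/17 percent for 24 h HR / HRV / impedance).
#'
#' @param baseline Named vector of channel baselines (bpm, bpm, ms, percent,
#'   per hour, percent of day, ohm).
#' @param daily_sd Day-to-day measurement noise SD per channel.
#' @param patient_sd Between-patient baseline SD per channel.
#' @param drift_per_day Pre-event drift rate per channel (same units per
#'   day); positive values increase toward the admission.
#' @param drift_days Days before an admission over which drift accumulates.
#' @param night_sd_rise Relative inflation of nocturnal-HR noise reached at
#'   the admission day (ramped over the final 84 days).
#' @param ahre_base Mean atrial burden (percent of 24 h) by group and
#'   AF-history status: named vector `event_af`, `event_noaf`, `control_af`,
#'   `control_noaf`.
#' @param ahre_rise Additive burden reached at admission (ramped over the
#'   final 84 days) for AF-history and non-AF event patients.
#' @return An object of class `telemetry_profile`.
#' @export
telemetry_profile <- function(baseline = c(hr24 = 70, night_hr = 60, hrv = 100,
                                           ahre_pct = 0, pvc_per_h = 5,
                                           activity = 10, impedance = 60),
                              daily_sd = c(hr24 = 0.8, night_hr = 2.2,
                                           hrv = 5, ahre_pct = 0,
                                           pvc_per_h = 3, activity = 2,
                                           impedance = 0.6),
                              patient_sd = c(hr24 = 7, night_hr = 6, hrv = 18,
                                             ahre_pct = 0, pvc_per_h = 4,
                                             activity = 3, impedance = 5),
                              drift_per_day = c(hr24 = 0.0566,
                                                night_hr = 0,
                                                hrv = -0.1738,
                                                ahre_pct = 0,
                                                pvc_per_h = 0.0247,
                                                activity = -0.0257,
                                                impedance = -0.0214),
                              drift_days = 240,
                              night_sd_rise = 0.25,
                              ahre_base = c(event_af = 18, event_noaf = 1.5,
                                            control_af = 20,
                                            control_noaf = 0.7),
                              ahre_rise = c(af = 20, noaf = 2)) {
  structure(list(baseline = baseline, daily_sd = daily_sd,
                 patient_sd = patient_sd, drift_per_day = drift_per_day,
                 drift_days = drift_days, night_sd_rise = night_sd_rise,
                 ahre_base = ahre_base, ahre_rise = ahre_rise),
            class = "telemetry_profile")
}

#' Simulate raw daily telemetry for a cohort
#'
#' Generates the seven physiologic channels in raw units with pre-event
#' drift for event patients (rising 24 h heart rate and PVC rate, falling
#' HRV, impedance and activity, rising atrial burden and nocturnal-HR
#' instability over the final weeks) and stationary series for controls.
#' Non-transmitted days carry `NA` measurements; HRV is additionally absent
#' on days dominated by atrial high-rate episodes (burden above 50 percent).
#'
#' @param patients,events As returned by [make_cohort()].
#' @param profile A [telemetry_profile()].
#' @param transmission_probability Daily transmission probability.
#' @param seed Integer seed (split deterministically per patient).
#' @return Data frame with columns `patient_id`, `day`, `hr24`, `night_hr`,
#'   `hrv`, `ahre_pct`, `pvc_per_h`, `activity`, `impedance`, `transmitted`.
#' @export
simulate_telemetry <- function(patients, events,
                               profile = telemetry_profile(),
                               transmission_probability = 0.9,
                               seed = 1L) {
  stopifnot(inherits(profile, "telemetry_profile"))
  ev_by_pat <- split(events$admission_day, events$patient_id)
  chans <- c("hr24", "night_hr", "hrv", "pvc_per_h", "activity", "impedance")
  out <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    grp <- patients$group[i]
    af <- patients$af_history[i]
    fu <- patients$follow_up_end[i]
    days <- 0:fu
    nd <- length(days)
    anchors <- if (grp == "event") sort(ev_by_pat[[pid]]) else integer(0)
    jj <- findInterval(days - 0.5, anchors) + 1L
    in_win <- jj <= length(anchors)
    offset <- rep(Inf, nd)
    offset[in_win] <- anchors[jj[in_win]] - days[in_win]

    set.seed(patient_seed(seed, pid) + 1)
    base_i <- profile$baseline + stats::rnorm(7) * profile$patient_sd
    names(base_i) <- names(profile$baseline)
    # drift accumulates linearly toward each admission
    dr <- pmax(0, profile$drift_days - offset)
    dr[!is.finite(dr)] <- 0
    vals <- sapply(chans, function(ch) {
      base_i[[ch]] + profile$drift_per_day[[ch]] * dr +
        stats::rnorm(nd) * profile$daily_sd[[ch]]
    })
    # nocturnal-HR instability: noise SD inflates over the final 12 weeks
    ramp84 <- pmax(0, 1 - offset / 84)
    ramp84[!is.finite(ramp84)] <- 0
    vals[, "night_hr"] <- base_i[["night_hr"]] +
      stats::rnorm(nd) * profile$daily_sd[["night_hr"]] *
        (1 + profile$night_sd_rise * ramp84)
    # atrial burden: skewed multiplicative noise around a patient level
    ab_key <- paste0(grp, if (af) "_af" else "_noaf")
    level <- profile$ahre_base[[ab_key]] * stats::runif(1, 0.5, 1.5)
    rise <- profile$ahre_rise[[if (af) "af" else "noaf"]]
    ahre_mean <- level + if (grp == "event") rise * ramp84 else 0
    ahre <- pmin(100, ahre_mean * exp(stats::rnorm(nd, 0, 0.8) - 0.32))
    vals[, "hrv"] <- pmax(vals[, "hrv"], 5)
    vals[, "pvc_per_h"] <- pmax(vals[, "pvc_per_h"], 0)
    vals[, "activity"] <- pmin(100, pmax(vals[, "activity"], 0))
    vals[, "impedance"] <- pmax(vals[, "impedance"], 25)
    transmitted <- stats::rbinom(nd, 1, transmission_probability)
    df <- data.frame(patient_id = pid, day = days,
                     hr24 = vals[, "hr24"], night_hr = vals[, "night_hr"],
                     hrv = vals[, "hrv"], ahre_pct = ahre,
                     pvc_per_h = vals[, "pvc_per_h"],
                     activity = vals[, "activity"],
                     impedance = vals[, "impedance"],
                     transmitted = transmitted,
                     stringsAsFactors = FALSE)
    df$hrv[df$ahre_pct > 50] <- NA  # HRV not computable under dominant AHRE
    meas <- c(chans, "ahre_pct")
    df[df$transmitted == 0, c("hr24", "night_hr", "hrv", "ahre_pct",
                              "pvc_per_h", "activity", "impedance")] <- NA
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screening fixture reproducing the reported eligibility cascade
#'
#' Builds the 5987-record screening population with single-reason exclusion
#' attributes matching the reported stepwise filter: 1654 records with an
#' unsuitable device or inactive remote monitoring, 391 with long-standing
#' persistent or permanent AF, 232 with LVEF above 35 percent, 221 with NYHA
#' class outside II/III, 1125 with insufficient remote-monitoring data, 314
#' with under 90 days of post-run-in follow-up and no event, and 2050 clean
#' records. Each excluded record fails exactly one stage.
#'
#' @return Data frame of 5987 screening records carrying the attributes
#'   tested by [apply_eligibility_cascade()], plus a `true_reason` column.
#' @export
make_filter_fixture <- function() {
  cc <- reference_cascade_counts()
  reasons <- c(rep("device_hm", cc[["device_hm"]]),
               rep("longstanding_af", cc[["longstanding_af"]]),
               rep("lvef", cc[["lvef"]]),
               rep("nyha", cc[["nyha"]]),
               rep("hm_data", cc[["hm_data"]]),
               rep("short_follow_up", cc[["short_follow_up"]]),
               rep("none", cc[["eligible"]]))
  n <- length(reasons)
  df <- data.frame(
    patient_id = sprintf("S%04d", seq_len(n)),
    device_ok = reasons != "device_hm",
    longstanding_af = reasons == "longstanding_af",
    lvef = ifelse(reasons == "lvef", 45L, 30L),
    nyha = ifelse(reasons == "nyha", "IV", "II"),
    hm_data_ok = reasons != "hm_data",
    followup_days_post_runin = ifelse(reasons == "short_follow_up", 60L, 400L),
    has_whfh = FALSE,
    true_reason = reasons,
    stringsAsFactors = FALSE
  )
  df
}

#' Simulate weekly observations directly from the mixed model
#'
#' Generates balanced event-anchored weekly data straight from the nested
#' random-intercept model's own generative form: fixed effects on time
#' (weeks since Week -12), group and their interaction, Gaussian patient and
#' anchor intercepts and residual noise. Used for inference-calibration
#' studies (type-I error, parameter-recovery bias) where the daily pipeline
#' is not the object under test.
#'
#' @param n_event_patients,n_control_patients Group sizes.
#' @param beta Fixed effects `c(intercept, time, group, time:group)`; the
#'   intercept is the control-group Week -12 mean.
#' @param varcomp Variance components `c(patient, anchor, residual)` as SDs
#'   in score points.
#' @param anchors_per_event_patient Integer vector recycled over event
#'   patients (default 1).
#' @param weeks Week indices (default -12:0).
#' @param seed Integer seed.
#' @return Data frame with `patient_id`, `anchor_id`, `group`, `week`,
#'   `mean_score`, `n_days_observed`.
#' @export
simulate_weekly_observations <- function(n_event_patients, n_control_patients,
                                         beta = c(30, 0, 12, 0.75),
                                         varcomp = c(patient = 15, anchor = 8,
                                                     residual = 6),
                                         anchors_per_event_patient = 1L,
                                         weeks = -12:0, seed = 1L) {
  set.seed(seed)
  n <- n_event_patients + n_control_patients
  group <- rep(c("event", "control"), c(n_event_patients, n_control_patients))
  ids <- sprintf("P%04d", seq_len(n))
  ka <- rep(1L, n)
  ka[group == "event"] <- rep_len(as.integer(anchors_per_event_patient),
                                  n_event_patients)
  pid <- rep(ids, ka)
  grp <- rep(group, ka)
  aid <- paste0(pid, "_a", unlist(lapply(ka, seq_len)))
  nw <- length(weeks)
  na <- length(aid)
  b_p <- rep(stats::rnorm(n, 0, varcomp[["patient"]]), ka)
  b_a <- stats::rnorm(na, 0, varcomp[["anchor"]])
  tt <- rep(weeks + 12, na)
  g <- rep(as.numeric(grp == "event"), each = nw)
  y <- beta[1] + beta[2] * tt + beta[3] * g + beta[4] * tt * g +
    rep(b_p + b_a, each = nw) + stats::rnorm(na * nw, 0, varcomp[["residual"]])
  data.frame(patient_id = rep(pid, each = nw),
             anchor_id = rep(aid, each = nw),
             group = rep(grp, each = nw),
             week = rep(weeks, na),
             mean_score = y,
             n_days_observed = 7L,
             stringsAsFactors = FALSE)
}
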