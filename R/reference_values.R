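# Endpoint summaries reported for the pooled development cohort of the
# score (2050 ICD/CRT-D patients from nine trials, 369 worsening-HF
# hospitalizations in 259 patients). These printed values are the inputs
# that calibrate the synthetic cohort generator and anchor the arithmetic
# checks; they are not estimated by this package.

#' Reported component-score endpoints of the development cohort
#'
#' Mean component scores (score points) of the composite at Week -12 and
#' Week 0 of the event-anchored analysis window, for patients hospitalized
#' for worsening heart failure (`event_*`, windows ending at admission) and
#' patients without such hospitalizations (`control_*`, windows ending at the
#' last remote transmission). Rows follow [score_components()]. The event
#' columns sum to composites of 42.3 and 51.6 points.
#'
#' @return A 7 x 4 numeric matrix with columns `event_w12`, `event_w0`,
#'   `control_w12`, `control_w0`.
#' @export
reference_component_means <- function() {
  m <- rbind(
    hr24     = c(13.7, 15.2, 12.1, 11.6),
    hrv      = c(9.3, 11.5, 4.5, 3.8),
    night_hr = c(7.1, 8.4, 6.4, 6.6),
    ti       = c(7.1, 8.7, 4.6, 4.7),
    activity = c(2.0, 2.5, 1.9, 1.6),
    ahre     = c(1.8, 3.0, 0.9, 1.0),
    pvc      = c(1.3, 2.3, 0.4, 0.3)
  )
  colnames(m) <- c("event_w12", "event_w0", "control_w12", "control_w0")
  m
}

#' Reported component-score standard deviations of the development cohort
#'
#' Cross-sectional standard deviations accompanying
#' [reference_component_means()], same layout.
#'
#' @return A 7 x 4 numeric matrix.
#' @export
reference_component_sds <- function() {
  m <- rbind(
    hr24     = c(6.1, 5.8, 5.3, 5.0),
    hrv      = c(16, 13.9, 7.6, 6.1),
    night_hr = c(5.4, 6.1, 4.6, 4.9),
    ti       = c(6.7, 6.9, 4.2, 4.2),
    activity = c(5.5, 6.9, 6.5, 6.2),
    ahre     = c(4.9, 6.0, 3.5, 3.9),
    pvc      = c(8.0, 10.6, 8.8, 8.5)
  )
  colnames(m) <- c("event_w12", "event_w0", "control_w12", "control_w0")
  m
}

#' Reported per-trial patient and event counts of the development cohort
#'
#' Patients meeting the selection criteria, patients with at least one
#' qualifying worsening-HF hospitalization, and qualifying hospitalizations,
#' by contributing trial. Totals: 2050 patients, 259 event patients,
#' 369 events.
#'
#' @return Data frame with columns `trial`, `n_patients`, `n_event_patients`,
#'   `n_events`.
#' @export
reference_trial_counts <- function() {
  data.frame(
    trial = c("SELENE HF", "BIO|Stream.HF", "EchoCRT", "ECOST-CRT",
              "HomeCARE II", "J-HomeCARE II", "DetectICI", "CASTLE-AF",
              "effecT"),
    n_patients = c(691, 408, 269, 205, 152, 121, 102, 66, 36),
    n_event_patients = c(80, 24, 38, 22, 38, 16, 9, 29, 3),
    n_events = c(112, 30, 64, 35, 46, 22, 12, 44, 4)
  )
}

#' Reported eligibility-cascade exclusion counts
#'
#' The stepwise screening of the pooled 5987-patient cohort: exclusions for
#' unsuitable device or inactive remote monitoring, long-standing persistent
#' or permanent atrial fibrillation, LVEF above 35 percent, NYHA class other
#' than II/III, insufficient remote-monitoring data, and under 90 days of
#' post-run-in follow-up without a qualifying hospitalization; 2050 patients
#' remain.
#'
#' @return Named integer vector of per-stage exclusion counts plus
#'   `eligible`.
#' @export
reference_cascade_counts <- function() {
  c(device_hm = 1654L, longstanding_af = 391L, lvef = 232L, nyha = 221L,
    hm_data = 1125L, short_follow_up = 314L, eligible = 2050L)
}
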