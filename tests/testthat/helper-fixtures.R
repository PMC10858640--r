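# Shared fixture builders; all data is generated in code at test time.

# A small cohort with daily component scores, anchors and weekly
# observations, for pipeline-level tests.
small_pipeline <- function(n_event = 30, n_control = 40, n_events_total = 40,
                           seed = 42) {
  cfg <- cohort_config(n_event_patients = n_event,
                       n_control_patients = n_control,
                       n_events_total = n_events_total,
                       follow_up_days = c(240L, 360L),
                       trial_allocation = NULL, seed = seed)
  ch <- make_cohort(cfg)
  sc <- simulate_component_scores(ch$patients, ch$events, seed = seed + 1)
  an <- select_anchors(ch$patients, ch$events, sc)
  wk <- extract_weekly_series(an, sc)
  list(config = cfg, patients = ch$patients, events = ch$events,
       scores = sc, anchors = an, weekly = wk)
}

# A constant-telemetry window of `n` fully transmitted days.
flat_window <- function(n = 84, hr24 = 70, night_hr = 60, hrv = 100,
                        ahre_pct = 0, pvc_per_h = 5, activity = 10,
                        impedance = 60) {
  data.frame(day = seq_len(n), hr24 = hr24, night_hr = night_hr, hrv = hrv,
             ahre_pct = ahre_pct, pvc_per_h = pvc_per_h, activity = activity,
             impedance = impedance, transmitted = 1)
}

# Reported event-group component means (Week -12 / Week 0), in engine order.
event_means_w12 <- function() reference_component_means()[, "event_w12"]
event_means_w0 <- function() reference_component_means()[, "event_w0"]
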