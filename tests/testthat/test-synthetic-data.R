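test_that("cohort generation is deterministic and conserves counts", {
  cfg <- cohort_config(n_event_patients = 12, n_control_patients = 20,
                       n_events_total = 17, follow_up_days = c(240L, 400L),
                       trial_allocation = NULL, seed = 5)
  a <- make_cohort(cfg)
  b <- make_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$patients), 32)
  expect_equal(sum(a$patients$group == "event"), 12)
  expect_equal(nrow(a$events), 17)
  expect_true(all(a$events$patient_id %in%
                    a$patients$patient_id[a$patients$group == "event"]))
  expect_true(all(a$events$admission_day <=
                    a$patients$follow_up_end[match(a$events$patient_id,
                                                   a$patients$patient_id)]))
  # generated records satisfy the eligibility criteria
  expect_true(all(a$patients$lvef <= 35))
  expect_true(all(a$patients$nyha %in% c("II", "III")))
})

test_that("an empty event group yields patients but no events", {
  cfg <- cohort_config(n_event_patients = 0, n_control_patients = 10,
                       n_events_total = NULL, trial_allocation = NULL,
                       seed = 2)
  ch <- make_cohort(cfg)
  expect_equal(nrow(ch$patients), 10)
  expect_equal(nrow(ch$events), 0)
})

test_that("default configuration reproduces the reported cohort accounting", {
  cfg <- cohort_config(seed = 3)
  ch <- make_cohort(cfg)
  expect_equal(nrow(ch$patients), 2050)
  expect_equal(length(unique(ch$events$patient_id)), 259)
  expect_equal(nrow(ch$events), 369)
  # per-trial allocation matches the reported counts exactly
  tt <- trial_tally(ch$patients, ch$events)
  ref <- reference_trial_counts()
  expect_equal(tt$n_patients[match(ref$trial, tt$trial)], ref$n_patients)
  expect_equal(tt$n_events[match(ref$trial, tt$trial)], ref$n_events)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_event_patients = -1), "non-negative")
  expect_error(cohort_config(transmission_probability = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(n_event_patients = 10, n_events_total = 50,
                             trial_allocation = NULL), "n_events_total")
  expect_error(trajectory_spec(residual_sd = -1), "non-negative")
})

test_that("noise-free control series sit exactly on the configured means", {
  cfg <- cohort_config(n_event_patients = 0, n_control_patients = 3,
                       n_events_total = NULL, follow_up_days = c(150L, 150L),
                       trial_allocation = NULL, seed = 8)
  ch <- make_cohort(cfg)
  mu <- reference_component_means()
  mu[, "control_w0"] <- mu[, "control_w12"]  # flat control trajectory
  tr <- trajectory_spec(means = mu, patient_sd = 0, anchor_sd = 0,
                        residual_sd = 0)
  sc <- simulate_component_scores(ch$patients, ch$events, tr,
                                  transmission_probability = 1, seed = 9)
  for (j in score_components()) {
    expect_equal(sc[[j]], rep(mu[j, "control_w12"], nrow(sc)))
  }
})

test_that("noise-free event trajectories average 51.6 over the final week", {
  cfg <- cohort_config(n_event_patients = 2, n_control_patients = 0,
                       n_events_total = 2, follow_up_days = c(240L, 300L),
                       trial_allocation = NULL, seed = 13)
  ch <- make_cohort(cfg)
  tr <- trajectory_spec(patient_sd = 0, anchor_sd = 0, residual_sd = 0)
  sc <- simulate_component_scores(ch$patients, ch$events, tr,
                                  transmission_probability = 1, seed = 14)
  for (i in seq_len(nrow(ch$events))) {
    ev <- ch$events[i, ]
    win <- sc$score[sc$patient_id == ev$patient_id &
                      sc$day >= ev$admission_day - 6 &
                      sc$day <= ev$admission_day]
    expect_equal(mean(win), 51.6)
    w12 <- sc$score[sc$patient_id == ev$patient_id &
                      sc$day >= ev$admission_day - 90 &
                      sc$day <= ev$admission_day - 84]
    expect_equal(mean(w12), 42.3)
  }
})

test_that("weekly score means converge to the configured endpoints", {
  pl <- small_pipeline(n_event = 250, n_control = 250, n_events_total = 300,
                       seed = 21)
  wk <- pl$weekly
  for (wt in list(list(week = -12, target = 42.3),
                  list(week = 0, target = 51.6))) {
    x <- wk$mean_score[wk$group == "event" & wk$week == wt$week]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - wt$target), 3 * se)
  }
})

test_that("component scores are non-negative with skew-heavy components", {
  pl <- small_pipeline(n_event = 10, n_control = 10, n_events_total = 12,
                       seed = 31)
  expect_true(all(as.matrix(pl$scores[, score_components()]) >= 0))
  expect_equal(pl$scores$score, rowSums(pl$scores[, score_components()]))
})

test_that("transmission flags follow the configured daily probability", {
  cfg <- cohort_config(n_event_patients = 0, n_control_patients = 40,
                       n_events_total = NULL, follow_up_days = c(200L, 200L),
                       trial_allocation = NULL, seed = 17)
  ch <- make_cohort(cfg)
  sc <- simulate_component_scores(ch$patients, ch$events,
                                  transmission_probability = 0.5, seed = 18)
  n <- nrow(sc)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(sc$transmitted) - 0.5), 3 * se)
  tel <- simulate_telemetry(ch$patients[1:5, ], ch$events,
                            transmission_probability = 1, seed = 19)
  expect_true(all(tel$transmitted == 1))
})

test_that("per-patient seed streams make subsets reproducible", {
  cfg <- cohort_config(n_event_patients = 4, n_control_patients = 4,
                       n_events_total = 5, follow_up_days = c(200L, 250L),
                       trial_allocation = NULL, seed = 23)
  ch <- make_cohort(cfg)
  full <- simulate_component_scores(ch$patients, ch$events, seed = 24)
  sub <- simulate_component_scores(ch$patients[3, , drop = FALSE],
                                   ch$events, seed = 24)
  pid <- ch$patients$patient_id[3]
  got <- full[full$patient_id == pid, ]
  rownames(got) <- rownames(sub) <- NULL
  expect_equal(got, sub)
})

test_that("stationary telemetry leaves the trend components near zero", {
  cfg <- cohort_config(n_event_patients = 6, n_control_patients = 0,
                       n_events_total = 6, follow_up_days = c(240L, 280L),
                       trial_allocation = NULL, seed = 25)
  ch <- make_cohort(cfg)
  prof <- telemetry_profile(drift_per_day = c(hr24 = 0, night_hr = 0,
                                              hrv = 0, ahre_pct = 0,
                                              pvc_per_h = 0, activity = 0,
                                              impedance = 0),
                            night_sd_rise = 0, ahre_rise = c(af = 0, noaf = 0))
  tel <- simulate_telemetry(ch$patients, ch$events, prof,
                            transmission_probability = 1, seed = 26)
  comps <- do.call(rbind, lapply(seq_len(nrow(ch$events)), function(i) {
    ev <- ch$events[i, ]
    w <- tel[tel$patient_id == ev$patient_id &
               tel$day > ev$admission_day - 84 &
               tel$day <= ev$admission_day, ]
    compute_components(w, engine_config())
  }))
  # pure-noise windows: trend statistics small relative to their weights
  for (j in c("hr24", "hrv", "ti", "activity", "pvc")) {
    expect_lt(mean(comps[[j]]), 2)
  }
})

test_that("the screening fixture partitions into the reported counts", {
  fx <- make_filter_fixture()
  expect_equal(nrow(fx), 5987)
  expect_equal(sum(fx$true_reason == "none"), 2050)
  cc <- reference_cascade_counts()
  tab <- table(fx$true_reason)
  for (nm in setdiff(names(cc), "eligible")) {
    expect_equal(unname(tab[[nm]]), unname(cc[[nm]]))
  }
})
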