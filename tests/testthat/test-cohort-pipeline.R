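test_that("the eligibility cascade reproduces the reported tally", {
  res <- apply_eligibility_cascade(make_filter_fixture())
  cc <- reference_cascade_counts()
  expect_equal(res$n_eligible, 2050)
  expect_equal(setNames(res$tally$n_excluded, res$tally$stage),
               cc[setdiff(names(cc), "eligible")])
  expect_equal(sum(res$tally$n_excluded) + res$n_eligible, 5987)
})

test_that("empty input passes through the cascade with zero tallies", {
  res <- apply_eligibility_cascade(make_filter_fixture()[0, ])
  expect_equal(res$n_eligible, 0)
  expect_true(all(res$tally$n_excluded == 0))
})

test_that("a record failing several stages is counted at the first", {
  fx <- make_filter_fixture()[1:10, ]
  fx$longstanding_af <- TRUE
  fx$lvef <- 50
  fx$device_ok <- TRUE
  res <- apply_eligibility_cascade(fx)
  tal <- setNames(res$tally$n_excluded, res$tally$stage)
  expect_equal(unname(tal["longstanding_af"]), 10)
  expect_equal(unname(tal["lvef"]), 0)
})

test_that("missing attributes name the failing stage", {
  fx <- make_filter_fixture()[1:5, ]
  fx$lvef <- NULL
  expect_error(apply_eligibility_cascade(fx), "stage 'lvef'")
})

test_that("anchor selection enforces run-in, gates and truncation rules", {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    group = c("event", "event", "control", "control"),
    implant_day = 0L, follow_up_end = c(400L, 400L, 400L, 100L),
    stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = c("A", "B", "B"),
    event_id = c("A_e1", "B_e1", "B_e2"),
    admission_day = c(20L, 200L, 260L),
    adjudicated = TRUE, stringsAsFactors = FALSE)
  daily <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i) {
    data.frame(patient_id = patients$patient_id[i],
               day = 0:patients$follow_up_end[i], transmitted = 1L)
  }))
  an <- select_anchors(patients, events, daily, engine_config())
  # A's event at day 20 violates the 30-day run-in
  expect_false("A_e1" %in% an$anchor_id)
  # B's repeat event 60 days after the first: truncated to the gap
  b2 <- an[an$anchor_id == "B_e2", ]
  expect_equal(b2$window_start_day, 200)
  expect_true(b2$truncated)
  expect_equal(b2$anchor_day - b2$window_start_day, 60)
  b1 <- an[an$anchor_id == "B_e1", ]
  expect_false(b1$truncated)
  # C qualifies as control; D has only 70 post-run-in days
  expect_true("C_c" %in% an$anchor_id)
  expect_false(any(an$patient_id == "D"))
})

test_that("the transmission gate excludes low-compliance anchors", {
  patients <- data.frame(patient_id = "E", group = "event",
                         implant_day = 0L, follow_up_end = 300L,
                         stringsAsFactors = FALSE)
  events <- data.frame(patient_id = "E", event_id = "E_e1",
                       admission_day = 200L, adjudicated = TRUE,
                       stringsAsFactors = FALSE)
  tx <- rep(c(1L, 0L), length.out = 301)  # 50% compliance
  daily <- data.frame(patient_id = "E", day = 0:300, transmitted = tx)
  an <- select_anchors(patients, events, daily, engine_config())
  expect_equal(nrow(an), 0)
})

test_that("day offsets 0..90 partition into 13 weekly bins of 7 days", {
  off <- 0:90
  week <- -(off %/% 7)
  expect_equal(sort(unique(week)), -12:0)
  expect_true(all(table(week) == 7))
  expect_equal(unique(week[off >= 84]), -12)
  expect_equal(unique(week[off <= 6]), 0)
})

test_that("weekly means reproduce constant and linear daily scores", {
  anchor <- data.frame(patient_id = "Z", anchor_id = "Z_e1", kind = "event",
                       event_id = "Z_e1", anchor_day = 200L,
                       window_start_day = 110L, truncated = FALSE,
                       group = "event", stringsAsFactors = FALSE)
  base <- data.frame(patient_id = "Z", day = 0:200, transmitted = 1L,
                     valid = TRUE, stringsAsFactors = FALSE)
  for (j in score_components()) base[[j]] <- 0
  # constant score
  d1 <- base; d1$score <- 7.5
  w1 <- extract_weekly_series(anchor, d1)
  expect_equal(nrow(w1), 13)
  expect_true(all(w1$mean_score == 7.5))
  expect_true(all(w1$n_days_observed == 7))
  # linear daily score: weekly means linear with slope 7x the daily slope
  d2 <- base; d2$score <- 0.3 * d2$day
  w2 <- extract_weekly_series(anchor, d2)
  w2 <- w2[order(w2$week), ]
  expect_equal(unique(round(diff(w2$mean_score), 10)), 0.3 * 7)
  # days 84-90 before the anchor land in week -12
  expect_equal(w2$mean_score[w2$week == -12], 0.3 * mean(200 - (84:90)))
})

test_that("truncated windows contribute only their covered weeks", {
  anchor <- data.frame(patient_id = "Z", anchor_id = "Z_e2", kind = "event",
                       event_id = "Z_e2", anchor_day = 200L,
                       window_start_day = 170L, truncated = TRUE,
                       group = "event", stringsAsFactors = FALSE)
  daily <- data.frame(patient_id = "Z", day = 0:200, transmitted = 1L,
                      valid = TRUE, score = 1, stringsAsFactors = FALSE)
  for (j in score_components()) daily[[j]] <- 1 / 7
  wk <- extract_weekly_series(anchor, daily)
  expect_equal(sort(unique(wk$week)), -4:0)  # offsets 0..30 only
  expect_error(extract_weekly_series(anchor,
                                     transform(daily, transmitted = 0L)),
               "no observed days")
})

test_that("weeks with no observed day are omitted, not zero-filled", {
  anchor <- data.frame(patient_id = "Z", anchor_id = "Z_e3", kind = "event",
                       event_id = "Z_e3", anchor_day = 150L,
                       window_start_day = 60L, truncated = FALSE,
                       group = "event", stringsAsFactors = FALSE)
  daily <- data.frame(patient_id = "Z", day = 0:150, transmitted = 1L,
                      valid = TRUE, score = 2, stringsAsFactors = FALSE)
  for (j in score_components()) daily[[j]] <- 2 / 7
  # knock out all of week -3 (offsets 21..27)
  daily$transmitted[150 - (21:27)] <- 0L  # day index offset by 1 row
  daily$transmitted[daily$day %in% (150 - 21:27)] <- 0L
  wk <- extract_weekly_series(anchor, daily)
  expect_false(-3 %in% wk$week)
  expect_equal(nrow(wk), 12)
})
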