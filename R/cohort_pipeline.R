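# Eligibility cascade, anchor selection (admissions or last transmission),
# run-in/transmission/repeat-event rules, and weekly aggregation of daily
# scores into the Week -12..0 observations the mixed model consumes.

cascade_stages <- function() {
  list(
    device_hm = list(cols = "device_ok",
                     fails = function(r) !r$device_ok),
    longstanding_af = list(cols = "longstanding_af",
                           fails = function(r) r$longstanding_af),
    lvef = list(cols = "lvef",
                fails = function(r) r$lvef > 35),
    nyha = list(cols = "nyha",
                fails = function(r) !(r$nyha %in% c("II", "III"))),
    hm_data = list(cols = "hm_data_ok",
                   fails = function(r) !r$hm_data_ok),
    short_follow_up = list(cols = c("followup_days_post_runin", "has_whfh"),
                           fails = function(r) {
                             !r$has_whfh & r$followup_days_post_runin < 90
                           })
  )
}

#' Apply the ordered eligibility cascade
#'
#' Screens patient records through the study's stepwise filter, in order:
#' unsuitable device or inactive remote monitoring, long-standing persistent
#' or permanent AF, LVEF above 35 percent, NYHA class outside II/III,
#' insufficient remote-monitoring data, and under 90 days of post-run-in
#' follow-up without a qualifying hospitalization. A record failing several
#' stages is counted only at the first failing stage.
#'
#' @param records Data frame carrying `device_ok`, `longstanding_af`,
#'   `lvef`, `nyha`, `hm_data_ok`, `followup_days_post_runin`, `has_whfh`.
#' @return List with `eligible` (the surviving records), `tally` (data frame
#'   of per-stage exclusion counts) and `n_eligible`.
#' @export
apply_eligibility_cascade <- function(records) {
  stages <- cascade_stages()
  for (nm in names(stages)) {
    missing <- setdiff(stages[[nm]]$cols, names(records))
    if (length(missing)) {
      stop("stage '", nm, "' requires missing column(s): ",
           paste(missing, collapse = ", "))
    }
  }
  remaining <- records
  counts <- integer(length(stages))
  names(counts) <- names(stages)
  for (nm in names(stages)) {
    if (nrow(remaining) == 0) break
    fail <- stages[[nm]]$fails(remaining)
    fail[is.na(fail)] <- FALSE
    counts[[nm]] <- sum(fail)
    remaining <- remaining[!fail, , drop = FALSE]
  }
  list(eligible = remaining,
       tally = data.frame(stage = names(stages), n_excluded = unname(counts)),
       n_eligible = nrow(remaining))
}

#' Select analysis anchors
#'
#' Event anchors are qualifying admission days: at least `run_in_days` after
#' implant and with a trailing transmission rate of at least
#' `min_transmission_rate` at the admission day. A repeat admission within
#' 90 days of the previous one has its window truncated to the inter-event
#' gap; a first admission within 90 days of the end of run-in gets the
#' available interval. Control anchors are the last transmitted day of
#' patients with no events, required to fall at least 90 days after the end
#' of run-in and to pass the same transmission gate.
#'
#' @param patients,events As returned by [make_cohort()].
#' @param daily Daily per-patient table carrying `patient_id`, `day` and
#'   `transmitted` (e.g. from [simulate_component_scores()] or
#'   [score_telemetry()]).
#' @param config An [engine_config()] (supplies the run-in length,
#'   transmission horizon and gate).
#' @return Data frame of anchors: `patient_id`, `anchor_id`, `kind`,
#'   `event_id`, `anchor_day`, `window_start_day`, `truncated`, `group`.
#' @export
select_anchors <- function(patients, events, daily,
                           config = engine_config()) {
  run_in <- config$run_in_days
  gate <- config$min_transmission_rate
  horizon <- config$transmission_horizon_days
  daily_by_pat <- split(daily[, c("day", "transmitted")], daily$patient_id)
  rows <- list()

  ev_pats <- unique(events$patient_id)
  for (pid in ev_pats) {
    ev <- events[events$patient_id == pid, , drop = FALSE]
    ev <- ev[order(ev$admission_day), , drop = FALSE]
    fu <- patients$follow_up_end[match(pid, patients$patient_id)]
    if (any(ev$admission_day > fu)) stop("event outside follow-up for ", pid)
    d <- daily_by_pat[[pid]]
    prev_day <- -Inf
    for (j in seq_len(nrow(ev))) {
      ad <- ev$admission_day[j]
      ok <- ad >= run_in
      if (ok) {
        tr <- transmission_rate(d$transmitted, d$day, ad, horizon)
        ok <- tr >= gate
      }
      if (ok) {
        ws <- max(ad - 90, run_in, if (is.finite(prev_day)) prev_day else -Inf)
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, anchor_id = ev$event_id[j], kind = "event",
          event_id = ev$event_id[j], anchor_day = ad,
          window_start_day = ws, truncated = (ad - ws) < 90,
          group = "event", stringsAsFactors = FALSE)
      }
      prev_day <- ad  # a skipped event still bounds the next window
    }
  }

  ctrl <- patients[patients$group == "control", , drop = FALSE]
  for (pid in ctrl$patient_id) {
    d <- daily_by_pat[[pid]]
    if (is.null(d) || !any(d$transmitted == 1)) next
    last_tx <- max(d$day[d$transmitted == 1])
    if (last_tx - run_in < 90) next
    tr <- transmission_rate(d$transmitted, d$day, last_tx, horizon)
    if (tr < gate) next
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = pid, anchor_id = paste0(pid, "_c"),
      kind = "last_transmission", event_id = NA_character_,
      anchor_day = last_tx, window_start_day = max(last_tx - 90, run_in),
      truncated = FALSE, group = "control", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), anchor_id = character(0),
                      kind = character(0), event_id = character(0),
                      anchor_day = integer(0), window_start_day = integer(0),
                      truncated = logical(0), group = character(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate daily scores into weekly observations
#'
#' Maps day offsets `d = anchor_day - day` (for `d` in 0..90 and days not
#' before the anchor's window start) to weeks `-floor(d/7)`, so Week 0 is
#' days 0-6 before the anchor and Week -12 is days 84-90. Each present week
#' is the mean of the composite score and of each component over the
#' observed (transmitted, valid) days in that bin; weeks with no observed
#' day are omitted, and truncated windows contribute only their covered
#' weeks.
#'
#' @param anchors As returned by [select_anchors()] (one or more rows).
#' @param daily Daily score table (e.g. from [simulate_component_scores()]
#'   or [score_telemetry()]) with `patient_id`, `day`, component columns,
#'   `score`, `valid`, `transmitted`.
#' @return Data frame of weekly observations: `patient_id`, `anchor_id`,
#'   `group`, `week`, `mean_score`, per-component means, `n_days_observed`.
#' @export
extract_weekly_series <- function(anchors, daily) {
  comp <- score_components()
  daily <- daily[, setdiff(names(daily), "group"), drop = FALSE]
  merged <- merge(daily, anchors[, c("patient_id", "anchor_id", "group",
                                     "anchor_day", "window_start_day")],
                  by = "patient_id")
  off <- merged$anchor_day - merged$day
  keep <- off >= 0 & off <= 90 & merged$day >= merged$window_start_day &
    merged$transmitted == 1 & merged$valid
  merged <- merged[keep, , drop = FALSE]
  if (nrow(merged) == 0) stop("no observed days fall inside any anchor window")
  merged$week <- -((merged$anchor_day - merged$day) %/% 7)
  key <- paste(merged$anchor_id, merged$week, sep = "@")
  agg <- stats::aggregate(merged[, c("score", comp)], by = list(key = key),
                          FUN = mean)
  nd <- as.integer(table(key)[agg$key])
  meta <- merged[!duplicated(key), c("patient_id", "anchor_id", "group",
                                     "week")]
  meta <- meta[match(agg$key, key[!duplicated(key)]), ]
  out <- data.frame(patient_id = meta$patient_id,
                    anchor_id = meta$anchor_id,
                    group = meta$group,
                    week = meta$week,
                    mean_score = agg$score,
                    agg[, comp, drop = FALSE],
                    n_days_observed = nd,
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$anchor_id, out$week), ]
  rownames(out) <- NULL
  out
}
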