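# Paper-shaped outputs: per-trial tallies, baseline comparison tables,
# component-contribution summaries and subgroup trend contrasts.

#' Per-trial patient and event tally
#'
#' Counts patients, patients with at least one qualifying hospitalization,
#' and hospitalizations per trial, with column percentages of the totals,
#' plus a `Total` row.
#'
#' @param patients,events As returned by [make_cohort()]; `patients` must
#'   carry a `trial` column.
#' @return Data frame with columns `trial`, `n_patients`, `pct_patients`,
#'   `n_event_patients`, `pct_event_patients`, `n_events`, `pct_events`.
#' @export
trial_tally <- function(patients, events) {
  if (!"trial" %in% names(patients)) stop("patients lack a 'trial' column")
  trials <- unique(patients$trial)
  ev_pats <- unique(events$patient_id)
  per <- lapply(trials, function(tr) {
    pats <- patients$patient_id[patients$trial == tr]
    data.frame(trial = tr,
               n_patients = length(pats),
               n_event_patients = sum(ev_pats %in% pats),
               n_events = sum(events$patient_id %in% pats))
  })
  out <- do.call(rbind, per)
  out <- out[order(-out$n_patients), ]
  tot <- data.frame(trial = "Total",
                    n_patients = sum(out$n_patients),
                    n_event_patients = sum(out$n_event_patients),
                    n_events = sum(out$n_events))
  out <- rbind(out, tot)
  pct <- function(x, total) round(100 * x / max(total, 1), 1)
  out$pct_patients <- pct(out$n_patients, tot$n_patients)
  out$pct_event_patients <- pct(out$n_event_patients, tot$n_event_patients)
  out$pct_events <- pct(out$n_events, tot$n_events)
  rownames(out) <- NULL
  out[, c("trial", "n_patients", "pct_patients", "n_event_patients",
          "pct_event_patients", "n_events", "pct_events")]
}

#' Component shares of the composite
#'
#' Expresses each component mean as a percentage of the composite mean
#' (their exact sum); shares sum to 100 before rounding.
#'
#' @param component_means Named numeric vector of the seven component means
#'   (names as [score_components()]).
#' @return Data frame with `component`, `mean`, `share_pct`, plus the
#'   composite mean as an attribute `composite`.
#' @export
component_shares <- function(component_means) {
  comp <- component_means[score_components()]
  if (anyNA(comp)) stop("all seven component means are required")
  composite <- sum(comp)
  if (composite <= 0) stop("composite mean must be positive")
  out <- data.frame(component = score_components(),
                    mean = unname(comp),
                    share_pct = unname(100 * comp / composite))
  attr(out, "composite") <- composite
  out
}

#' Contribution summary at a given week and group
#'
#' Averages the component scores of the weekly observations of one group at
#' one week and reports each component's share of the composite mean.
#'
#' @param weekly_observations As from [extract_weekly_series()].
#' @param group Group label to summarize.
#' @param week Week index in -12..0.
#' @return As [component_shares()], with attributes `composite`, `group`,
#'   `week`, `n_observations`.
#' @export
contribution_summary <- function(weekly_observations, group, week) {
  sel <- weekly_observations[weekly_observations$group == group &
                               weekly_observations$week == week, ,
                             drop = FALSE]
  if (nrow(sel) == 0) stop("no observations for that group and week")
  means <- colMeans(sel[, score_components(), drop = FALSE])
  out <- component_shares(means)
  attr(out, "group") <- group
  attr(out, "week") <- week
  attr(out, "n_observations") <- nrow(sel)
  out
}

#' Baseline-characteristics comparison table
#'
#' Compares covariates between the two groups the way baseline tables in
#' this field are built: continuous covariates as median (IQR) with a
#' Mann-Whitney U test (tie-corrected normal approximation, no continuity
#' correction), categorical covariates as n (percent of non-missing) with
#' Pearson's chi-square test (no continuity correction).
#'
#' @param patients Data frame with a `group` column and the covariates.
#' @param variables Character vector of covariate column names (default: a
#'   standard set of demographics and comorbidities present in
#'   [make_cohort()] output).
#' @return Data frame with one row per covariate (or covariate level):
#'   `variable`, `type`, `summary_event`, `summary_control`, `p_value`.
#' @export
baseline_comparison <- function(patients,
                                variables = c("age", "sex", "bmi", "nyha",
                                              "lvef", "af_history",
                                              "renal_insufficiency",
                                              "ischaemic", "device")) {
  stopifnot("group" %in% names(patients))
  g <- patients$group
  rows <- list()
  for (v in variables) {
    if (!v %in% names(patients)) stop("covariate '", v, "' not found")
    x <- patients[[v]]
    if (all(is.na(x))) stop("covariate '", v, "' is entirely missing")
    if (is.numeric(x)) {
      fmt <- function(z) {
        q <- stats::quantile(z, c(0.25, 0.5, 0.75), na.rm = TRUE)
        sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
      }
      pv <- stats::wilcox.test(x[g == "event"], x[g == "control"],
                               exact = FALSE, correct = FALSE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, type = "continuous",
        summary_event = fmt(x[g == "event"]),
        summary_control = fmt(x[g == "control"]),
        p_value = pv, stringsAsFactors = FALSE)
    } else {
      x <- as.character(x)
      keep <- !is.na(x)
      tab <- table(x[keep], g[keep])
      pv <- if (nrow(tab) > 1 && all(dim(tab) > 0)) {
        suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else NA_real_
      for (lev in rownames(tab)) {
        ne <- tab[lev, "event"]
        nc <- tab[lev, "control"]
        rows[[length(rows) + 1L]] <- data.frame(
          variable = if (nrow(tab) == 2 && lev == rownames(tab)[1]) v else
            paste0(v, ": ", lev),
          type = "categorical",
          summary_event = sprintf("%d (%.1f)", ne,
                                  100 * ne / sum(tab[, "event"])),
          summary_control = sprintf("%d (%.1f)", nc,
                                    100 * nc / sum(tab[, "control"])),
          p_value = pv, stringsAsFactors = FALSE)
        if (nrow(tab) == 2) break   # dichotomies: report the first level only
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard subgroup dichotomies
#'
#' The pre-specified baseline dichotomies of the trend analysis: age below
#' or at-least 75 years, sex, body-mass index below or at-least 30, AF
#' history, renal insufficiency, and ischaemic aetiology.
#'
#' @return Named list of functions, each mapping a patients data frame to a
#'   two-level factor.
#' @export
default_subgroup_specs <- function() {
  list(
    age = function(p) factor(ifelse(p$age >= 75, ">=75", "<75"),
                             levels = c("<75", ">=75")),
    sex = function(p) factor(p$sex, levels = c("female", "male")),
    bmi = function(p) factor(ifelse(p$bmi >= 30, ">=30", "<30"),
                             levels = c("<30", ">=30")),
    af_history = function(p) factor(ifelse(p$af_history, "yes", "no"),
                                    levels = c("no", "yes")),
    renal_insufficiency = function(p)
      factor(ifelse(p$renal_insufficiency, "yes", "no"),
             levels = c("no", "yes")),
    ischaemic = function(p) factor(ifelse(p$ischaemic, "ischaemic",
                                          "non-ischaemic"),
                                   levels = c("non-ischaemic", "ischaemic"))
  )
}

#' Subgroup trend contrasts among event patients
#'
#' For each subgroup dichotomy, fits the nested random-intercept model to
#' the event-group weekly observations with the subgroup level replacing the
#' event/control indicator, and reports the Week -12 (intercept) and weekly
#' slope contrasts between the two levels.
#'
#' @param weekly_observations As from [extract_weekly_series()]; only rows
#'   with `group == "event"` are used.
#' @param patients Patient table carrying the subgroup covariates.
#' @param specs Named list of level-assignment functions (default
#'   [default_subgroup_specs()]).
#' @param response Response column (default `"mean_score"`).
#' @return Data frame with one row per subgroup and contrast: `subgroup`,
#'   `level0`, `level1`, `contrast`, `estimate`, `se`, `z`, `p_value`,
#'   `n_patients_level0`, `n_patients_level1`.
#' @export
subgroup_trend_report <- function(weekly_observations, patients,
                                  specs = default_subgroup_specs(),
                                  response = "mean_score") {
  obs <- weekly_observations[weekly_observations$group == "event", ,
                             drop = FALSE]
  if (nrow(obs) == 0) stop("no event-group observations")
  rows <- list()
  for (nm in names(specs)) {
    lv <- specs[[nm]](patients)
    obs$level <- as.character(lv[match(obs$patient_id, patients$patient_id)])
    levs <- levels(lv)
    npat <- vapply(levs, function(l)
      length(unique(obs$patient_id[obs$level == l])), integer(1))
    if (any(npat < 2)) {
      stop("subgroup '", nm, "' has a level with fewer than 2 patients")
    }
    fit <- fit_nested_lmm(obs, response = response, group_var = "level",
                          event_level = levs[2])
    wc <- wald_contrasts(fit)
    wc$subgroup <- nm
    wc$level0 <- levs[1]
    wc$level1 <- levs[2]
    wc$n_patients_level0 <- npat[1]
    wc$n_patients_level1 <- npat[2]
    rows[[length(rows) + 1L]] <- wc
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("subgroup", "level0", "level1", "contrast", "estimate", "se", "z",
          "p_value", "n_patients_level0", "n_patients_level1")]
}
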