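# New-user cohort assembly, censoring, early/late treatment stages,
# combination summaries with small-cell suppression, multiplicity counts
# and calendar-period timelines.

#' Identify new users and their index dates
#'
#' A patient's index date is their first redemption of a study drug inside
#' the enrollment window with no study-drug redemption in the washout
#' window strictly preceding it: a prior redemption `g` days before the
#' index excludes the patient iff `0 < g < washout_days` (one exactly
#' `washout_days` before does not). Patients whose first in-window
#' redemption fails the washout are excluded. When birthdates are given,
#' patients who do not reach `age_threshold_years` for at least one day
#' during the study window are excluded as well.
#'
#' @param records Calendar-dated records (`patient_id`, `atc`, `date`).
#' @param config A [study_config()]; supplies the enrollment window,
#'   washout length, study-drug ATC prefixes and age threshold.
#' @param birthdates Optional `data.table(patient_id, birthdate)`.
#' @param registry_start First date the register covers; defaults to the
#'   earliest record. The register must reach back at least `washout_days`
#'   before the enrollment window start, otherwise washout status is
#'   unknowable and an error is raised.
#'
#' @return `data.table(patient_id, index_date)`, one row per new user.
#' @export
identify_new_users <- function(records, config = study_config(),
                               birthdates = NULL, registry_start = NULL) {
  dt <- data.table::as.data.table(records)
  study <- dt[Reduce(`|`, lapply(config$atc_prefixes, startsWith,
                                 x = dt$atc))]
  if (nrow(study) == 0L)
    stop("no study-drug redemptions match the configured ATC prefixes")
  if (is.null(registry_start)) registry_start <- min(study$date)
  if (as.Date(registry_start) > config$study_window[1] - config$washout_days)
    stop("register does not span the washout period: it must start on or ",
         "before ", config$study_window[1] - config$washout_days)
  data.table::setorder(study, patient_id, date)
  idx <- study[, {
    inw <- date >= config$study_window[1] & date <= config$study_window[2]
    if (!any(inw)) {
      NULL
    } else {
      cand <- date[which(inw)[1L]]
      gaps <- as.integer(cand - date)
      if (any(gaps > 0L & gaps < config$washout_days)) NULL
      else .(index_date = cand)
    }
  }, by = patient_id]
  if (!is.null(birthdates)) {
    bd <- data.table::as.data.table(birthdates)
    idx <- merge(idx, bd, by = "patient_id", all.x = TRUE)
    thr <- vapply(idx$birthdate, function(b) {
      lt <- as.POSIXlt(b)
      lt$year <- lt$year + config$age_threshold_years
      as.numeric(as.Date(lt))
    }, numeric(1))
    keep <- is.na(idx$birthdate) |
      as.Date(thr, origin = "1970-01-01") <= config$study_window[2]
    idx <- idx[keep, .(patient_id, index_date)]
  }
  data.table::setorder(idx, patient_id)
  idx[]
}

#' Truncate intervals at censoring
#'
#' Intervals (medication events, episodes or co-exposure periods) are
#' truncated at `min(censor_day - 1, followup_days - 1)`: a patient
#' censored on day `c` contributes coverage up to day `c - 1` only, and a
#' censor day of 0 removes the patient entirely. Rows emptied by the
#' truncation are dropped, and any `n_days`/`total_days` column is
#' recomputed.
#'
#' @param intervals `data.table` with `patient_id`, `start_day`, `end_day`.
#' @param censoring `data.table(patient_id, censor_day)` (optionally a
#'   `cause` column); patients without a row are censored at the end of
#'   follow-up.
#' @param followup_days Follow-up length.
#' @return Truncated copy of `intervals`.
#' @export
apply_censoring <- function(intervals, censoring = NULL,
                            followup_days = 730L) {
  out <- data.table::copy(data.table::as.data.table(intervals))
  cap <- rep(as.integer(followup_days) - 1L, nrow(out))
  if (!is.null(censoring) && nrow(censoring)) {
    cz <- data.table::as.data.table(censoring)
    stopifnot(all(cz$censor_day >= 0L), all(cz$censor_day <= followup_days))
    m <- match(out$patient_id, cz$patient_id)
    cap <- pmin(cap, ifelse(is.na(m), cap, cz$censor_day[m] - 1L))
  }
  out[, end_day := pmin(end_day, cap)]
  out <- out[start_day <= end_day]
  for (col in intersect(c("n_days", "total_days"), names(out)))
    out[, (col) := interval_days(start_day, end_day)]
  out[]
}

#' Split co-exposure periods into early and late treatment stages
#'
#' Clips each period to the early window (internal days
#' `0 .. early_end - 1`, i.e. reported days 1..`early_end`) and the late
#' window (`early_end .. followup_days - 1`). A combination is *incident*
#' in the stage containing its first co-exposed day for that agent set, so
#' early + late clipped days of any period always equal its total days.
#'
#' @param periods `data.table(patient_id, agent_set, start_day, end_day,
#'   ...)`.
#' @param early_end First-stage length in days (reported days
#'   1..`early_end`).
#' @param followup_days Follow-up length.
#' @return `data.table(patient_id, agent_set, n_agents, stage, start_day,
#'   end_day, n_days, incident_stage)` with `stage` in
#'   `c("early", "late")`.
#' @export
stage_split <- function(periods, early_end = 180L, followup_days = 730L) {
  stopifnot(early_end > 0L, early_end < followup_days)
  empty <- data.table::data.table(
    patient_id = character(), agent_set = character(), n_agents = integer(),
    stage = character(), start_day = integer(), end_day = integer(),
    n_days = integer(), incident_stage = character())
  if (nrow(periods) == 0L) return(empty)
  dt <- data.table::as.data.table(periods)
  windows <- data.table::data.table(
    stage = c("early", "late"),
    w_start = c(0L, as.integer(early_end)),
    w_end = c(as.integer(early_end) - 1L, as.integer(followup_days) - 1L))
  out <- data.table::rbindlist(lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i]
    clip <- dt[, .(patient_id, agent_set,
                   stage = w$stage,
                   start_day = pmax(start_day, w$w_start),
                   end_day = pmin(end_day, w$w_end))]
    clip[start_day <= end_day]
  }))
  if (!nrow(out)) return(empty)
  out[, n_days := interval_days(start_day, end_day)]
  out[, n_agents := n_agents(agent_set)]
  first_day <- dt[, .(first_day = min(start_day)),
                  by = .(patient_id, agent_set)]
  first_day[, incident_stage := ifelse(first_day < early_end,
                                       "early", "late")]
  out <- merge(out, first_day[, .(patient_id, agent_set, incident_stage)],
               by = c("patient_id", "agent_set"))
  data.table::setcolorder(out, c("patient_id", "agent_set", "n_agents",
                                 "stage", "start_day", "end_day", "n_days",
                                 "incident_stage"))
  data.table::setorder(out, patient_id, agent_set, stage, start_day)
  out[]
}

# Mask counts below the disclosure threshold; returns display strings.
suppress_display <- function(n, min_cell_size) {
  ifelse(n < min_cell_size, paste0("<", min_cell_size),
         format(n, trim = TRUE, scientific = FALSE))
}

#' Ranked combination-frequency table for one treatment stage
#'
#' For every agent set incident in the stage: the number of distinct
#' patients, their share of all patients with any co-exposed day in the
#' stage, and the median (Q1-Q3) of per-patient total stage-clipped
#' co-exposure days for that set (quartiles by linear interpolation
#' between order statistics). Rows with fewer than `min_cell_size`
#' patients are suppressed: counts are rendered as `"<5"` and numeric
#' summaries withheld. Ranking is by patient count descending, ties broken
#' by agent-set label.
#'
#' @param staged Output of [stage_split()].
#' @param stage `"early"` or `"late"`.
#' @param min_cell_size Disclosure threshold.
#' @param k_top Keep only the top `k_top` rows (default: all).
#' @param denominator `"stage_coexposed"` (default: all patients with any
#'   co-exposed day in the stage) or `"incident"` (patients with any
#'   combination incident in the stage).
#' @return `data.table(rank, agent_set, n_agents, n_patients, n_display,
#'   pct_patients, median_days, q1_days, q3_days)`; `n_patients` and the
#'   summaries are `NA` in suppressed rows.
#' @export
summarize_combinations <- function(staged, stage = c("early", "late"),
                                   min_cell_size = 5L, k_top = Inf,
                                   denominator = c("stage_coexposed",
                                                   "incident")) {
  stage <- match.arg(stage)
  denominator <- match.arg(denominator)
  st <- stage
  dt <- data.table::as.data.table(staged)
  empty <- data.table::data.table(
    rank = integer(), agent_set = character(), n_agents = integer(),
    n_patients = integer(), n_display = character(),
    pct_patients = numeric(), median_days = numeric(), q1_days = numeric(),
    q3_days = numeric())
  inc <- dt[stage == st & incident_stage == st]
  if (!nrow(inc)) return(empty)
  denom <- if (denominator == "stage_coexposed")
    data.table::uniqueN(dt[stage == st, patient_id])
  else data.table::uniqueN(inc$patient_id)
  per_pat <- inc[, .(days = sum(n_days)), by = .(agent_set, patient_id)]
  tab <- per_pat[, .(
    n_patients = .N,
    median_days = as.numeric(stats::quantile(days, 0.5, type = 7)),
    q1_days = as.numeric(stats::quantile(days, 0.25, type = 7)),
    q3_days = as.numeric(stats::quantile(days, 0.75, type = 7))
  ), by = agent_set]
  data.table::setorder(tab, -n_patients, agent_set)
  tab[, rank := .I]
  tab[, n_agents := n_agents(agent_set)]
  tab[, pct_patients := 100 * n_patients / denom]
  tab[, n_display := suppress_display(n_patients, min_cell_size)]
  sup <- tab$n_patients < min_cell_size
  for (col in c("n_patients", "pct_patients", "median_days", "q1_days",
                "q3_days"))
    tab[sup, (col) := NA]
  data.table::setcolorder(tab, c("rank", "agent_set", "n_agents",
                                 "n_patients", "n_display", "pct_patients",
                                 "median_days", "q1_days", "q3_days"))
  utils::head(tab[], k_top)
}

#' Patient counts by co-exposure multiplicity
#'
#' For each patient with at least one co-exposed day in the stage, the
#' multiplicity is the size of the largest agent set with coverage in the
#' stage; counts are reported per multiplicity (capped as `"<cap>+"`) with
#' small cells suppressed.
#'
#' @param staged Output of [stage_split()].
#' @param stage `"early"` or `"late"`.
#' @param min_cell_size Disclosure threshold.
#' @param cap Multiplicities `>= cap` are pooled into one `"cap+"` row.
#' @return `data.table(multiplicity, n_patients, n_display, pct)`.
#' @export
multiplicity_counts <- function(staged, stage = c("early", "late"),
                                min_cell_size = 5L, cap = 4L) {
  stage <- match.arg(stage)
  st <- stage
  dt <- data.table::as.data.table(staged)[stage == st]
  empty <- data.table::data.table(multiplicity = character(),
                                  n_patients = integer(),
                                  n_display = character(), pct = numeric())
  if (!nrow(dt)) return(empty)
  per_pat <- dt[, .(mult = max(n_agents)), by = patient_id]
  per_pat[, bucket := ifelse(mult >= cap, paste0(cap, "+"),
                             as.character(mult))]
  total <- nrow(per_pat)
  tab <- per_pat[, .(n_patients = .N), by = .(multiplicity = bucket)]
  data.table::setorder(tab, multiplicity)
  tab[, pct := 100 * n_patients / total]
  tab[, n_display := suppress_display(n_patients, min_cell_size)]
  sup <- tab$n_patients < min_cell_size
  tab[sup, c("n_patients", "pct") := .(NA_integer_, NA_real_)]
  data.table::setcolorder(tab, c("multiplicity", "n_patients", "n_display",
                                 "pct"))
  tab[]
}

#' Top combinations per calendar period and stage
#'
#' Bins patients by index year into calendar periods, and within each
#' period and treatment stage ranks agent sets by the number of patients
#' with incident co-exposure; combinations below the disclosure threshold
#' are excluded from the ranking.
#'
#' @param staged Output of [stage_split()].
#' @param index_dates `data.table(patient_id, index_date)`.
#' @param period_bins List of length-2 integer vectors `c(first_year,
#'   last_year)`; must be non-overlapping and cover every observed index
#'   year. Defaults to 1996-2000, 2001-2005, 2006-2010, 2011-2015,
#'   2016-2018.
#' @param n_top Number of top combinations per bin and stage.
#' @param min_cell_size Disclosure threshold.
#' @return Long `data.table(period, stage, rank, agent_set, n_patients)`.
#' @export
timeline_top5 <- function(staged, index_dates,
                          period_bins = list(c(1996L, 2000L),
                                             c(2001L, 2005L),
                                             c(2006L, 2010L),
                                             c(2011L, 2015L),
                                             c(2016L, 2018L)),
                          n_top = 5L, min_cell_size = 5L) {
  dt <- data.table::as.data.table(staged)
  period_bins <- period_bins[order(vapply(period_bins, `[`, 1L, i = 1L))]
  idx <- data.table::as.data.table(index_dates)
  idx[, year := as.integer(format(index_date, "%Y"))]
  yrs <- unlist(lapply(period_bins, function(b) seq.int(b[1], b[2])))
  if (anyDuplicated(yrs)) stop("calendar period bins overlap")
  uncovered <- setdiff(unique(idx$year), yrs)
  if (length(uncovered))
    stop("index year(s) not covered by any calendar bin: ",
         paste(sort(uncovered), collapse = ", "))
  labs <- vapply(period_bins, function(b)
    paste0(b[1], "-", b[2]), character(1))
  idx[, period := labs[findInterval(year, vapply(period_bins, `[`, 1L,
                                                 i = 1L))]]
  dt <- merge(dt, idx[, .(patient_id, period)], by = "patient_id")
  inc <- dt[stage == incident_stage]
  counts <- inc[, .(n_patients = data.table::uniqueN(patient_id)),
                by = .(period, stage, agent_set)]
  counts <- counts[n_patients >= min_cell_size]
  data.table::setorder(counts, period, stage, -n_patients, agent_set)
  counts[, rank := seq_len(.N), by = .(period, stage)]
  out <- counts[rank <= n_top,
                .(period, stage, rank, agent_set, n_patients)]
  data.table::setorder(out, period, stage, rank)
  out[]
}
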