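# Synthetic prescription-redemption register with known ground truth,
# the brute-force day-resolution oracle, and the accuracy-evaluation
# harness that mirrors the study's validation design (a random sample of
# patients whose co-exposure start and end dates are checked exactly).

#' Specify a simulated medication regimen
#'
#' Describes how one group of simulated patients redeems prescriptions:
#' which products, the true supply duration(s) per pack, refill timing
#' noise, start offsets, optional discontinuation, and random
#' non-persistence gaps.
#'
#' @param agents Character vector of product ATC codes.
#' @param durations List (one element per agent) of candidate true pack
#'   supply durations in days; a single numeric vector is recycled.
#' @param duration_probs Optional list of sampling probabilities matching
#'   `durations`.
#' @param jitter Maximum refill-timing noise in days: each refill interval
#'   is the dispensed duration plus a uniform integer in `[-jitter,
#'   jitter]`.
#' @param refill_gap_prob Probability that a refill is followed by an
#'   additional non-persistence gap.
#' @param gap_range Length-2 integer vector: uniform range (days) of the
#'   injected gaps.
#' @param start_offsets Integer vector (recycled): day each agent is
#'   started, relative to the index date.
#' @param discontinue_day Integer vector (recycled): last day on which an
#'   agent may still be redeemed; `NA` for no discontinuation.
#' @param fdc_components Named list mapping any fixed-dose combination
#'   codes in `agents` to their component agent vectors.
#'
#' @return An object of class `regimen_spec`.
#' @export
regimen_spec <- function(agents, durations = list(c(28L, 84L)),
                         duration_probs = NULL, jitter = 3L,
                         refill_gap_prob = 0.25, gap_range = c(90L, 330L),
                         start_offsets = 0L, discontinue_day = NA_integer_,
                         fdc_components = NULL) {
  agents <- as.character(agents)
  if (!is.list(durations)) durations <- list(durations)
  durations <- rep_len(durations, length(agents))
  if (!is.null(duration_probs)) {
    if (!is.list(duration_probs)) duration_probs <- list(duration_probs)
    duration_probs <- rep_len(duration_probs, length(agents))
  }
  stopifnot(all(unlist(durations) >= 1), jitter >= 0,
            refill_gap_prob >= 0, refill_gap_prob <= 1,
            length(gap_range) == 2L, gap_range[1] <= gap_range[2])
  structure(list(
    agents = agents,
    durations = lapply(durations, as.integer),
    duration_probs = duration_probs,
    jitter = as.integer(jitter),
    refill_gap_prob = refill_gap_prob,
    gap_range = as.integer(gap_range),
    start_offsets = rep_len(as.integer(start_offsets), length(agents)),
    discontinue_day = rep_len(as.integer(discontinue_day), length(agents)),
    fdc_components = fdc_components
  ), class = "regimen_spec")
}

#' Default regimen mix for the synthetic register
#'
#' A mixture of single-drug, two- to four-drug free-dose, and fixed-dose
#' regimens over first-line antihypertensive agents (thiazide with
#' potassium, amlodipine, enalapril, losartan, and the
#' perindopril/amlodipine fixed-dose product C09BB04). Pack durations are
#' drawn from the two market pack sizes {28, 84} days; a quarter of
#' refills are followed by a 90-330 day non-persistence gap, matching the
#' working assumption of the duration estimator's 0.8 trim percentile
#' that roughly the top fifth of waiting times are gaps rather than
#' supply.
#'
#' @return List of `list(spec = regimen_spec, weight = numeric)`.
#' @export
default_regimen_mix <- function() {
  fdc <- list(C09BB04 = c("C08CA01", "C09AA04"))
  dur <- list(c(28L, 84L))
  pr <- list(c(0.6, 0.4))
  list(
    list(spec = regimen_spec("C03AB01", dur, pr), weight = 0.25),
    list(spec = regimen_spec(c("C03AB01", "C08CA01"), dur, pr,
                             start_offsets = c(0L, 30L)), weight = 0.20),
    list(spec = regimen_spec(c("C03AB01", "C09AA02"), dur, pr,
                             start_offsets = c(0L, 60L)), weight = 0.15),
    list(spec = regimen_spec(c("C03AB01", "C08CA01", "C09AA02"), dur, pr,
                             start_offsets = c(0L, 14L, 90L)),
         weight = 0.12),
    list(spec = regimen_spec(c("C03AB01", "C08CA01", "C09AA02", "C09CA01"),
                             dur, pr,
                             start_offsets = c(0L, 14L, 60L, 120L),
                             discontinue_day = c(NA, NA, NA, 300L)),
         weight = 0.08),
    list(spec = regimen_spec("C09BB04", dur, pr, fdc_components = fdc),
         weight = 0.10),
    list(spec = regimen_spec(c("C09BB04", "C03AB01"), dur, pr,
                             start_offsets = c(0L, 45L),
                             fdc_components = fdc), weight = 0.10)
  )
}

# Simulate one agent's redemption days and dispensed durations.
simulate_refills <- function(spec, k, followup_days) {
  t <- spec$start_offsets[k]
  disc <- spec$discontinue_day[k]
  durs <- spec$durations[[k]]
  probs <- if (is.null(spec$duration_probs)) NULL else spec$duration_probs[[k]]
  days <- integer(); disp <- integer()
  while (t < followup_days && (is.na(disc) || t <= disc)) {
    d <- if (length(durs) == 1L) durs else
      sample(durs, 1L, prob = probs)
    days <- c(days, t); disp <- c(disp, d)
    iv <- d + if (spec$jitter > 0L)
      sample(seq.int(-spec$jitter, spec$jitter), 1L) else 0L
    if (stats::runif(1) < spec$refill_gap_prob)
      iv <- iv + sample(seq.int(spec$gap_range[1], spec$gap_range[2]), 1L)
    t <- t + max(1L, iv)
  }
  list(days = days, dispensed = disp)
}

# True supplied-day coverage runs for one agent: pour each dispensed
# duration from its redemption day with same-drug carry-over, cap at the
# end of follow-up.
pour_supply <- function(days, dispensed, followup_days) {
  cap <- followup_days - 1L
  C <- -1L
  starts <- integer(); ends <- integer()
  for (i in seq_along(days)) {
    s <- max(days[i], C + 1L)
    C <- max(C, days[i] - 1L) + dispensed[i]
    if (s <= min(C, cap)) {
      starts <- c(starts, s); ends <- c(ends, min(C, cap))
    }
  }
  runs_from_days(runs_to_days(starts, ends))
}

#' Generate a synthetic prescription-redemption register
#'
#' Draws each patient's regimen from a weighted mix, simulates per-agent
#' refill sequences with pack-size variation, timing jitter and injected
#' non-persistence gaps, and records the ground-truth supplied-day
#' coverage for every patient and product. A fraction of patients are
#' washout violators (an extra study-drug redemption in the year before
#' their index date) and some patients receive decoy redemptions after
#' the end of follow-up; both exercise the cohort filters and are flagged
#' in the output. Identical seeds produce identical registers.
#'
#' @param n_patients Number of (non-decoy-only) patients.
#' @param regimen_mix List of `list(spec, weight)`; see
#'   [default_regimen_mix()].
#' @param followup_days Follow-up length in days.
#' @param calendar_window Length-2 `Date` vector from which index dates
#'   are drawn uniformly.
#' @param seed Integer seed.
#' @param washout_violator_frac Fraction of patients given a pre-index
#'   redemption violating the washout.
#' @param post_followup_decoy_frac Fraction of patients given a decoy
#'   redemption after the end of follow-up.
#' @param washout_days Washout length used to place violator decoys.
#'
#' @return List with `events` (day-indexed redemptions, all patients),
#'   `records` (calendar-dated register including decoy rows), `truth`
#'   (per-product true coverage runs), `truth_durations` (per-redemption
#'   dispensed durations), `cohort` (`patient_id`, `index_date`,
#'   `regimen`, `eligible`, `n_agents`), `fdc_map`, and `params`.
#' @export
generate_register <- function(n_patients,
                              regimen_mix = default_regimen_mix(),
                              followup_days = 730L,
                              calendar_window = as.Date(c("1996-01-01",
                                                          "2016-12-31")),
                              seed = 20240101,
                              washout_violator_frac = 0.05,
                              post_followup_decoy_frac = 0.05,
                              washout_days = 365L) {
  if (!length(regimen_mix)) stop("regimen mix must not be empty")
  w <- vapply(regimen_mix, `[[`, numeric(1), "weight")
  stopifnot(all(w > 0))
  set.seed(seed)

  fdc_map <- list()
  for (rm in regimen_mix)
    for (nm in names(rm$spec$fdc_components))
      fdc_map[[nm]] <- rm$spec$fdc_components[[nm]]

  n_days_window <- as.integer(calendar_window[2] - calendar_window[1])
  ev <- list(); tr <- list(); td <- list(); extra <- list()
  cohort <- vector("list", n_patients)

  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%05d", p)
    ridx <- sample.int(length(regimen_mix), 1L, prob = w)
    spec <- regimen_mix[[ridx]]$spec
    eligible <- stats::runif(1) >= washout_violator_frac
    if (eligible) {
      index_date <- calendar_window[1] + sample.int(n_days_window + 1L,
                                                    1L) - 1L
    } else {
      # washout violator: index near the enrollment window start, with a
      # pre-window study-drug redemption less than washout_days earlier
      offset <- sample.int(min(300L, washout_days - 2L), 1L) - 1L
      index_date <- calendar_window[1] + offset
      gap <- if (offset + 1L >= washout_days - 1L) washout_days - 1L
      else sample(seq.int(offset + 1L, washout_days - 1L), 1L)
      extra[[length(extra) + 1L]] <- data.table::data.table(
        patient_id = pid, atc = spec$agents[1L], date = index_date - gap)
    }
    agent_set <- character()
    for (k in seq_along(spec$agents)) {
      a <- spec$agents[k]
      rf <- simulate_refills(spec, k, followup_days)
      if (!length(rf$days)) next
      keep <- rf$days < followup_days
      ev[[length(ev) + 1L]] <- data.table::data.table(
        patient_id = pid, atc = a, day = rf$days[keep])
      td[[length(td) + 1L]] <- data.table::data.table(
        patient_id = pid, atc = a, day = rf$days[keep],
        duration_days = rf$dispensed[keep])
      runs <- pour_supply(rf$days[keep], rf$dispensed[keep], followup_days)
      if (nrow(runs)) {
        runs[, `:=`(patient_id = pid, atc = a)]
        tr[[length(tr) + 1L]] <- runs
      }
      agent_set <- c(agent_set,
                     if (a %in% names(fdc_map)) fdc_map[[a]] else a)
    }
    if (stats::runif(1) < post_followup_decoy_frac) {
      extra[[length(extra) + 1L]] <- data.table::data.table(
        patient_id = pid, atc = spec$agents[1L],
        date = index_date + followup_days + sample.int(60L, 1L) + 4L)
    }
    cohort[[p]] <- data.table::data.table(
      patient_id = pid, index_date = index_date, regimen = ridx,
      eligible = eligible, n_agents = length(unique(agent_set)))
  }

  events <- data.table::rbindlist(ev)
  events <- unique(events, by = c("patient_id", "atc", "day"))
  data.table::setorder(events, patient_id, day, atc)
  cohort <- data.table::rbindlist(cohort)
  truth <- data.table::rbindlist(tr)
  data.table::setcolorder(truth, c("patient_id", "atc", "start_day",
                                   "end_day"))
  truth_durations <- data.table::rbindlist(td)

  records <- merge(events, cohort[, .(patient_id, index_date)],
                   by = "patient_id")
  records <- records[, .(patient_id, atc, date = index_date + day)]
  if (length(extra))
    records <- data.table::rbindlist(list(records,
                                          data.table::rbindlist(extra)),
                                     use.names = TRUE)
  records <- unique(records, by = c("patient_id", "atc", "date"))
  data.table::setorder(records, patient_id, date, atc)

  list(events = events[], records = records[], truth = truth[],
       truth_durations = truth_durations[], cohort = cohort[],
       fdc_map = fdc_map,
       params = list(n_patients = n_patients, seed = seed,
                     followup_days = followup_days,
                     calendar_window = calendar_window,
                     washout_violator_frac = washout_violator_frac,
                     post_followup_decoy_frac = post_followup_decoy_frac))
}

#' Brute-force day-resolution co-exposure oracle
#'
#' Enumerates, for every patient, the set of agents covering each day of
#' follow-up (expanding fixed-dose products to their components) and
#' declares a day co-exposed iff at least two distinct agents cover it.
#' Contiguous runs of co-exposed days are the oracle's final episodes.
#' Feeding it the pipeline's own treatment episodes validates the interval
#' algebra in isolation (episode mode); feeding it the generator's ground
#' truth validates the whole pipeline including duration estimation
#' (truth mode).
#'
#' @param coverage `data.table(patient_id, atc, start_day, end_day)` —
#'   treatment episodes or true coverage runs per product.
#' @param fdc_map Named list mapping fixed-dose codes to component agents.
#' @param count_fdc_alone If `FALSE`, a day is co-exposed only when at
#'   least two distinct *products* cover it.
#' @return List with `final_episodes` (`data.table(patient_id,
#'   episode_index, start_day, end_day, total_days)`) and `totals`
#'   (`data.table(patient_id, total_days)`, all patients in `coverage`).
#' @export
day_level_oracle <- function(coverage, fdc_map = NULL,
                             count_fdc_alone = TRUE) {
  cov <- data.table::as.data.table(coverage)
  per_patient <- function(eps) {
    prods <- unique(eps$atc)
    agent_days <- list()
    prod_days <- list()
    for (a in prods) {
      d <- runs_to_days(eps[atc == a]$start_day, eps[atc == a]$end_day)
      d <- unique(d)
      prod_days[[a]] <- d
      comps <- if (a %in% names(fdc_map)) fdc_map[[a]] else a
      for (cmp in comps)
        agent_days[[cmp]] <- c(agent_days[[cmp]], d)
    }
    all_days <- unlist(lapply(agent_days, unique), use.names = FALSE)
    if (!length(all_days)) return(integer())
    tab <- table(all_days)
    co <- as.integer(names(tab))[tab >= 2L]
    if (!count_fdc_alone) {
      ptab <- table(unlist(prod_days, use.names = FALSE))
      co <- intersect(co, as.integer(names(ptab))[ptab >= 2L])
    }
    sort(co)
  }
  pids <- unique(cov$patient_id)
  finals <- list(); totals <- vector("list", length(pids))
  for (i in seq_along(pids)) {
    co <- per_patient(cov[patient_id == pids[i]])
    runs <- runs_from_days(co)
    totals[[i]] <- data.table::data.table(patient_id = pids[i],
                                          total_days = length(co))
    if (nrow(runs)) {
      runs[, `:=`(patient_id = pids[i], episode_index = seq_len(.N),
                  total_days = interval_days(start_day, end_day))]
      finals[[length(finals) + 1L]] <- runs
    }
  }
  fe <- if (length(finals)) data.table::rbindlist(finals)
  else data.table::data.table(start_day = integer(), end_day = integer(),
                              patient_id = character(),
                              episode_index = integer(),
                              total_days = integer())
  data.table::setcolorder(fe, c("patient_id", "episode_index", "start_day",
                                "end_day", "total_days"))
  list(final_episodes = fe[], totals = data.table::rbindlist(totals))
}

#' Day-level oracle for every agent combination
#'
#' For each patient, intersects the day coverage of every subset of two or
#' more agents and returns the maximal runs — the brute-force counterpart
#' of [pairwise_co_exposure()] plus [find_overlaps()] for free-dose
#' regimens.
#'
#' @inheritParams day_level_oracle
#' @return `data.table(patient_id, agent_set, start_day, end_day,
#'   n_days)`.
#' @export
oracle_combination_periods <- function(coverage, fdc_map = NULL) {
  cov <- data.table::as.data.table(coverage)
  out <- list()
  for (pid in unique(cov$patient_id)) {
    eps <- cov[patient_id == pid]
    agent_days <- list()
    for (a in unique(eps$atc)) {
      d <- unique(runs_to_days(eps[atc == a]$start_day,
                               eps[atc == a]$end_day))
      comps <- if (a %in% names(fdc_map)) fdc_map[[a]] else a
      for (cmp in comps)
        agent_days[[cmp]] <- unique(c(agent_days[[cmp]], d))
    }
    ags <- names(agent_days)
    if (length(ags) < 2L) next
    for (k in 2:length(ags)) {
      combs <- utils::combn(ags, k, simplify = FALSE)
      for (s in combs) {
        inter <- Reduce(intersect, agent_days[s])
        runs <- runs_from_days(inter)
        if (nrow(runs)) {
          runs[, `:=`(patient_id = pid, agent_set = agent_key(s),
                      n_days = interval_days(start_day, end_day))]
          out[[length(out) + 1L]] <- runs
        }
      }
    }
  }
  if (!length(out))
    return(data.table::data.table(patient_id = character(),
                                  agent_set = character(),
                                  start_day = integer(),
                                  end_day = integer(), n_days = integer()))
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("patient_id", "agent_set", "start_day",
                                 "end_day", "n_days"))
  data.table::setorder(res, patient_id, agent_set, start_day)
  res[]
}

#' Accuracy of co-exposure start/end classification against the oracle
#'
#' Draws a random sample of eligible patients and scores each as correct
#' iff every final co-exposure episode start and end date produced by the
#' interval-based method matches the day-level oracle exactly (patients
#' with no co-exposure in both are correct). Reports the percentage of
#' correctly classified patients.
#'
#' @param pipeline_final `data.table(patient_id, start_day, end_day, ...)`
#'   final episodes from [compute_coexposure()].
#' @param oracle_final Final episodes from [day_level_oracle()].
#' @param eligible_ids Patient ids to sample from (typically patients who
#'   redeemed at least two distinct agents).
#' @param sample_size Number of patients to audit (default 400). If fewer
#'   are eligible, all are audited with a warning.
#' @param seed Integer seed for the sample draw.
#' @return List with `accuracy_pct`, `n_evaluated`, `n_correct`, and
#'   `discrepancies` (`data.table(patient_id)` of mismatching patients).
#' @export
evaluate_accuracy <- function(pipeline_final, oracle_final, eligible_ids,
                              sample_size = 400L, seed = 1L) {
  eligible_ids <- unique(as.character(eligible_ids))
  if (!length(eligible_ids)) stop("no eligible patients to evaluate")
  if (length(eligible_ids) < sample_size) {
    warning(sprintf("only %d eligible patients; evaluating all of them",
                    length(eligible_ids)), call. = FALSE)
    sample_ids <- eligible_ids
  } else {
    set.seed(seed)
    sample_ids <- sample(eligible_ids, sample_size)
  }
  pf <- data.table::as.data.table(pipeline_final)
  of <- data.table::as.data.table(oracle_final)
  intervals_of <- function(dt, pid) {
    sub <- dt[patient_id == pid, .(start_day, end_day)]
    data.table::setorder(sub, start_day)
    sub
  }
  ok <- vapply(sample_ids, function(pid)
    isTRUE(all.equal(intervals_of(pf, pid), intervals_of(of, pid),
                     check.attributes = FALSE)), logical(1))
  list(accuracy_pct = 100 * mean(ok),
       n_evaluated = length(sample_ids),
       n_correct = sum(ok),
       discrepancies = data.table::data.table(
         patient_id = sample_ids[!ok]))
}
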