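#' Study configuration
#'
#' Bundles the design parameters of a register-based co-exposure study:
#' new-user washout, follow-up length, early/late stage boundary, the
#' permissible gap used when merging medication events into treatment
#' episodes, duration-estimation settings, and the disclosure threshold
#' for aggregated output.
#'
#' Days are handled on a 0-based internal grid: day 0 is the index date
#' (the first qualifying redemption) and the follow-up window covers days
#' `0 .. followup_days - 1`. All intervals are closed at both ends, so an
#' interval `[s, e]` covers `e - s + 1` days.
#'
#' @param washout_days Length of the pre-index window that must be free of
#'   study-drug redemptions for a patient to qualify as a new user. A prior
#'   redemption strictly less than `washout_days` before the index excludes
#'   the patient; one exactly `washout_days` before does not.
#' @param followup_days Follow-up length in days from the index date.
#' @param early_stage_end_day Last day (1-based, as usually reported) of the
#'   early treatment stage; internally the early window is days
#'   `0 .. early_stage_end_day - 1`.
#' @param permissible_gap_days Maximum supply-free gap, in days, allowed
#'   inside one treatment episode.
#' @param min_cell_size Smallest count that may be disclosed in aggregated
#'   tables; counts in `1 .. min_cell_size - 1` are suppressed.
#' @param age_threshold_years Minimum age (reached for at least one day
#'   during the study window) for cohort eligibility, applied when
#'   birthdates are available.
#' @param study_window Length-2 `Date` vector: enrollment window (first and
#'   last admissible index date).
#' @param atc_prefixes Character vector of ATC prefixes defining the study
#'   drugs (prefix match).
#' @param trim_percentile Fraction of the refill waiting-time distribution
#'   retained when fitting the duration estimator; waiting times above this
#'   empirical quantile are discarded as non-persistence gaps.
#' @param k_range Candidate numbers of clusters for the waiting-time
#'   clustering step.
#' @param duration_statistic `"median"` or `"mean"`: the within-cluster
#'   statistic used as the assigned supply duration.
#' @param default_duration_days Duration assigned when no waiting times are
#'   available for a drug at all.
#' @param count_fdc_alone Should a single fixed-dose combination product,
#'   with no other concurrent medication, count as co-exposure? Defaults to
#'   `TRUE`: its estimated duration is by definition a period of concurrent
#'   exposure to its components.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `study_config` (a validated named list).
#' @export
study_config <- function(washout_days = 365L,
                         followup_days = 730L,
                         early_stage_end_day = 180L,
                         permissible_gap_days = 30L,
                         min_cell_size = 5L,
                         age_threshold_years = 65L,
                         study_window = as.Date(c("1996-01-01", "2016-12-31")),
                         atc_prefixes = c("C03A", "C08CA", "C09AA", "C09BB",
                                          "C09CA", "C09DB"),
                         trim_percentile = 0.8,
                         k_range = 2:10,
                         duration_statistic = c("median", "mean"),
                         default_duration_days = 30L,
                         count_fdc_alone = TRUE,
                         seed = NULL) {
  duration_statistic <- match.arg(duration_statistic)
  cfg <- list(
    washout_days = as.integer(washout_days),
    followup_days = as.integer(followup_days),
    early_stage_end_day = as.integer(early_stage_end_day),
    permissible_gap_days = if (is.finite(permissible_gap_days))
      as.integer(permissible_gap_days) else Inf,
    min_cell_size = as.integer(min_cell_size),
    age_threshold_years = as.integer(age_threshold_years),
    study_window = as.Date(study_window),
    atc_prefixes = as.character(atc_prefixes),
    trim_percentile = as.numeric(trim_percentile),
    k_range = as.integer(k_range),
    duration_statistic = duration_statistic,
    default_duration_days = as.integer(default_duration_days),
    count_fdc_alone = isTRUE(count_fdc_alone),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  validate_study_config(structure(cfg, class = "study_config"))
}

validate_study_config <- function(cfg) {
  stopifnot(
    cfg$washout_days >= 0,
    cfg$followup_days >= 1,
    cfg$early_stage_end_day > 0,
    cfg$early_stage_end_day < cfg$followup_days,
    is.infinite(cfg$permissible_gap_days) || cfg$permissible_gap_days >= 0,
    cfg$min_cell_size >= 1,
    length(cfg$study_window) == 2L,
    !anyNA(cfg$study_window),
    cfg$study_window[1] <= cfg$study_window[2],
    cfg$trim_percentile > 0, cfg$trim_percentile <= 1,
    all(cfg$k_range >= 1),
    cfg$default_duration_days >= 1
  )
  cfg
}

#' Read a study configuration from a YAML file
#'
#' Keys mirror the arguments of [study_config()]; unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$study_window)) raw$study_window <- as.Date(raw$study_window)
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("Co-exposure study configuration\n")
  cat(sprintf("  washout: %d d | follow-up: %d d | early stage: days 1-%d\n",
              x$washout_days, x$followup_days, x$early_stage_end_day))
  cat(sprintf("  permissible gap: %s d | min cell: %d | age threshold: %d y\n",
              format(x$permissible_gap_days), x$min_cell_size,
              x$age_threshold_years))
  cat(sprintf("  enrollment window: %s .. %s\n",
              x$study_window[1], x$study_window[2]))
  cat(sprintf("  SEE: trim %.2f, k in %d..%d, %s durations\n",
              x$trim_percentile, min(x$k_range), max(x$k_range),
              x$duration_statistic))
  invisible(x)
}
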