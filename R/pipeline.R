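# End-to-end pipeline: cohort -> durations -> episodes -> co-exposure ->
# final episodes -> stage summaries, with every intermediate table
# written to disk for audit.

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  cat(msg, "\n", sep = "")
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full co-exposure pipeline
#'
#' Executes, in order: register reading, new-user identification with
#' washout, conversion to follow-up day indices, duration estimation,
#' per-drug treatment-episode construction, censoring truncation,
#' co-exposure period and final-episode computation, stage splitting, and
#' combination/multiplicity/timeline summaries. All intermediate tables
#' are written as CSV into `out_dir` together with a run log (row counts
#' per stage) and a YAML snapshot of the configuration.
#'
#' @param register Either a path to a register CSV or a records
#'   `data.table` (`patient_id`, `atc`, `date`).
#' @param config A [study_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing artifacts.
#' @param fdc_map Named list mapping fixed-dose ATC codes to component
#'   agents.
#' @param censoring Optional `data.table(patient_id, censor_day)`.
#' @param birthdates Optional `data.table(patient_id, birthdate)`.
#' @param registry_start Passed to [identify_new_users()].
#'
#' @return (Invisibly) a list with `index_dates`, `models`, `med_events`,
#'   `episodes`, `periods`, `final_episodes`, `staged`, `summary_early`,
#'   `summary_late`, `multiplicity_early`, `multiplicity_late`,
#'   `timeline`.
#' @export
run_pipeline <- function(register, config = study_config(), out_dir = NULL,
                         fdc_map = NULL, censoring = NULL,
                         birthdates = NULL, registry_start = NULL) {
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(con), add = TRUE)
    yaml::write_yaml(lapply(unclass(config), function(x)
      if (inherits(x, "Date")) format(x) else x),
      file.path(out_dir, "config.yaml"))
  }
  emit <- function(dt, name) {
    if (!is.null(out_dir))
      data.table::fwrite(dt, file.path(out_dir, paste0(name, ".csv")))
    dt
  }

  records <- if (is.character(register))
    read_register(register, config) else data.table::as.data.table(register)
  log_line(con, "records: %d rows, %d patients", nrow(records),
           data.table::uniqueN(records$patient_id))
  log_line(con,
           "parameters: washout=%d followup=%d gap=%s early_stage=%d",
           config$washout_days, config$followup_days,
           format(config$permissible_gap_days), config$early_stage_end_day)

  index_dates <- identify_new_users(records, config, birthdates,
                                    registry_start)
  emit(index_dates, "index_dates")
  log_line(con, "new users: %d", nrow(index_dates))

  events <- to_relative_days(records[patient_id %in%
                                       index_dates$patient_id],
                             index_dates, config)
  log_line(con, "in-window redemptions: %d (dropped %d post-follow-up)",
           nrow(events), attr(events, "n_dropped_post_followup"))

  see <- fit_see_register(events, config)
  emit(see$events, "medication_events")
  if (!is.null(out_dir))
    write_see_models(see$models, file.path(out_dir, "see_models.json"))
  log_line(con, "SEE models fitted for %d drugs; %d medication events",
           length(see$models), nrow(see$events))

  episodes <- build_all_episodes(see$events, config$permissible_gap_days,
                                 config$followup_days)
  episodes <- apply_censoring(episodes, censoring, config$followup_days)
  emit(episodes, "treatment_episodes")
  log_line(con, "treatment episodes: %d", nrow(episodes))

  co <- compute_coexposure(episodes, fdc_map, config$count_fdc_alone)
  emit(co$periods, "coexposure_periods")
  emit(co$final_episodes, "final_episodes")
  log_line(con, "co-exposure periods: %d; final episodes: %d (%d patients)",
           nrow(co$periods), nrow(co$final_episodes),
           data.table::uniqueN(co$final_episodes$patient_id))

  staged <- stage_split(co$periods, config$early_stage_end_day,
                        config$followup_days)
  emit(staged, "staged_periods")

  summary_early <- emit(summarize_combinations(
    staged, "early", config$min_cell_size), "summary_early")
  summary_late <- emit(summarize_combinations(
    staged, "late", config$min_cell_size), "summary_late")
  multiplicity_early <- emit(multiplicity_counts(
    staged, "early", config$min_cell_size), "multiplicity_early")
  multiplicity_late <- emit(multiplicity_counts(
    staged, "late", config$min_cell_size), "multiplicity_late")

  timeline <- tryCatch(
    emit(timeline_top5(staged, index_dates,
                       min_cell_size = config$min_cell_size), "timeline"),
    error = function(e) {
      log_line(con, "timeline skipped: %s", conditionMessage(e))
      NULL
    })

  log_line(con, "pipeline complete")
  invisible(list(index_dates = index_dates, models = see$models,
                 med_events = see$events, episodes = episodes,
                 periods = co$periods, final_episodes = co$final_episodes,
                 staged = staged, summary_early = summary_early,
                 summary_late = summary_late,
                 multiplicity_early = multiplicity_early,
                 multiplicity_late = multiplicity_late,
                 timeline = timeline))
}
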