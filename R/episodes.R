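# Treatment-episode construction: merge one patient-drug's medication
# events into maximal intervals of presumed continuous use, with
# carry-over of unused supply for the same medication, a permissible gap,
# and a hard cap at the end of follow-up.

#' Build treatment episodes for one patient-drug event sequence
#'
#' Processes medication events in redemption order while maintaining a
#' running coverage end `C` (carry-over: refilling before the current
#' supply is exhausted shifts the unused supply forward). For an event
#' redeemed on day `t` with duration `d`:
#'
#' * if `t <= C + permissible_gap + 1`, the event joins the current episode
#'   and `C <- max(C, t - 1) + d` — a redemption the day after coverage
#'   ends is a 0-day gap;
#' * otherwise the episode closes at `min(C, followup_days - 1)` and a new
#'   episode opens at `t`.
#'
#' Supply accumulates without bound inside an episode, but coverage is
#' truncated at the end of follow-up, so total episode days per
#' patient-drug never exceed `followup_days`. With
#' `permissible_gap = Inf` every event sequence forms a single episode.
#'
#' @param start_days Integer vector of redemption days, sorted ascending,
#'   all in `[0, followup_days)`.
#' @param duration_days Integer vector of supply durations (days, >= 1),
#'   same length as `start_days`.
#' @param permissible_gap Maximum supply-free gap (days) allowed inside one
#'   episode; may be `Inf`.
#' @param followup_days Follow-up length; coverage is capped at day
#'   `followup_days - 1`.
#'
#' @return `data.table(episode_index, start_day, end_day, n_events)` with
#'   pairwise disjoint episodes separated by gaps strictly greater than
#'   `permissible_gap`.
#' @export
build_episodes <- function(start_days, duration_days, permissible_gap = 30,
                           followup_days = 730L) {
  n <- length(start_days)
  if (n == 0L)
    return(data.table::data.table(episode_index = integer(),
                                  start_day = integer(), end_day = integer(),
                                  n_events = integer()))
  stopifnot(length(duration_days) == n, all(duration_days >= 1))
  start_days <- as.integer(start_days)
  if (is.unsorted(start_days)) stop("events must be sorted by start_day")
  if (start_days[1L] < 0L || start_days[n] >= followup_days)
    stop("event start days must lie in [0, followup_days)")

  cap <- as.integer(followup_days) - 1L
  ep_start <- integer(); ep_end <- integer(); ep_n <- integer()
  cur_start <- start_days[1L]
  C <- start_days[1L] + duration_days[1L] - 1L
  cur_n <- 1L
  if (n > 1L) for (i in 2:n) {
    t <- start_days[i]; d <- duration_days[i]
    if (t <= C + permissible_gap + 1L) {
      C <- max(C, t - 1L) + d
      cur_n <- cur_n + 1L
    } else {
      ep_start <- c(ep_start, cur_start)
      ep_end <- c(ep_end, min(C, cap))
      ep_n <- c(ep_n, cur_n)
      cur_start <- t
      C <- t + d - 1L
      cur_n <- 1L
    }
  }
  ep_start <- c(ep_start, cur_start)
  ep_end <- c(ep_end, min(C, cap))
  ep_n <- c(ep_n, cur_n)
  data.table::data.table(episode_index = seq_along(ep_start),
                         start_day = ep_start, end_day = as.integer(ep_end),
                         n_events = ep_n)
}

#' Build treatment episodes for every patient-drug in an event table
#'
#' Applies [build_episodes()] within each `(patient_id, atc)` group.
#'
#' @param events `data.table(patient_id, atc, start_day, duration_days,
#'   ...)` as returned by [assign_durations()] / [fit_see_register()].
#' @param permissible_gap,followup_days See [build_episodes()].
#' @return `data.table(patient_id, atc, episode_index, start_day, end_day,
#'   n_events)`.
#' @export
build_all_episodes <- function(events, permissible_gap = 30,
                               followup_days = 730L) {
  if (nrow(events) == 0L)
    return(data.table::data.table(patient_id = character(), atc = character(),
                                  episode_index = integer(),
                                  start_day = integer(), end_day = integer(),
                                  n_events = integer()))
  dt <- data.table::as.data.table(events)
  data.table::setorder(dt, patient_id, atc, start_day)
  out <- dt[, build_episodes(start_day, duration_days, permissible_gap,
                             followup_days),
            by = .(patient_id, atc)]
  out[]
}
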