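library(data.table)

# Episode table for a single patient-drug from (start, end) pairs.
ep <- function(..., patient = "P1", atc = "A") {
  iv <- list(...)
  data.table(patient_id = patient, atc = atc,
             episode_index = seq_along(iv),
             start_day = vapply(iv, `[`, numeric(1), 1L),
             end_day = vapply(iv, `[`, numeric(1), 2L),
             n_events = 1L)
}

# Co-exposure period table from (agents, start, end) triples.
per <- function(..., patient = NULL) {
  rows <- lapply(list(...), function(x)
    data.table(agent_set = agent_key(x[[1]]),
               start_day = as.integer(x[[2]]), end_day = as.integer(x[[3]])))
  out <- rbindlist(rows)
  out[, n_days := end_day - start_day + 1L]
  if (!is.null(patient)) out[, patient_id := patient]
  out[]
}

# Independent day-enumeration oracle for the episode builder: pour each
# event's supply day by day (unused supply shifts forward, never across a
# gap), cap coverage at follow-up, then group covered runs into episodes
# separated by uncovered gaps strictly greater than the permissible gap.
pour_oracle_episodes <- function(start_days, durations, gap, followup) {
  covered <- logical(followup)
  C <- -1L
  for (i in seq_along(start_days)) {
    s <- max(start_days[i], C + 1L)
    C <- max(C, start_days[i] - 1L) + durations[i]
    if (s <= min(C, followup - 1L))
      covered[(s:min(C, followup - 1L)) + 1L] <- TRUE
  }
  days <- which(covered) - 1L
  if (!length(days))
    return(data.table(start_day = integer(), end_day = integer()))
  brk <- which(diff(days) > gap + 1L)
  data.table(start_day = days[c(1L, brk + 1L)],
             end_day = days[c(brk, length(days))])
}

# Write a small register CSV and return its path.
write_toy_register <- function(lines, file = tempfile(fileext = ".csv")) {
  writeLines(c("patient_id,atc,date", lines), file)
  file
}
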