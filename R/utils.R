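# Shared small helpers: canonical agent-set keys and interval arithmetic.

# Separator for canonical agent-set labels; ATC codes never contain "+".
AGENT_SEP <- "+"

#' Canonical key for a set of agents
#'
#' Sorts, deduplicates and joins agent codes into a single label, so that a
#' combination of agents has exactly one name regardless of input order.
#'
#' @param agents Character vector of agent (ATC) codes.
#' @return Length-1 character key, e.g. `"C03AB01+C08CA01"`.
#' @export
agent_key <- function(agents) {
  paste(sort(unique(as.character(agents))), collapse = AGENT_SEP)
}

#' Split a canonical agent-set key back into its agent codes
#'
#' @param key Character vector of keys produced by [agent_key()].
#' @return For a single key, a character vector of codes; for several keys,
#'   a list of such vectors.
#' @export
agents_from_key <- function(key) {
  out <- strsplit(as.character(key), AGENT_SEP, fixed = TRUE)
  if (length(out) == 1L) out[[1]] else out
}

# Number of agents in each canonical key (vectorised).
n_agents <- function(key) {
  lengths(strsplit(as.character(key), AGENT_SEP, fixed = TRUE))
}

#' Merge agent sets into one canonical sorted set
#'
#' Takes any collection of agent sets (character vectors and/or canonical
#' keys) and returns their union as a sorted vector of codes. Idempotent.
#'
#' @param sets A list of character vectors, or a character vector of
#'   canonical keys / codes.
#' @return Sorted character vector of distinct agent codes.
#' @export
combine_pairs <- function(sets) {
  if (!is.list(sets)) sets <- as.list(sets)
  if (!length(sets)) stop("combine_pairs() needs at least one agent set")
  codes <- unlist(lapply(sets, function(s)
    unlist(strsplit(as.character(s), AGENT_SEP, fixed = TRUE))),
    use.names = FALSE)
  sort(unique(codes))
}

# Closed-interval length on the day grid: [s, e] covers e - s + 1 days.
interval_days <- function(start, end) {
  pmax(0L, as.integer(end) - as.integer(start) + 1L)
}

# Turn integer days into maximal contiguous runs (closed intervals).
runs_from_days <- function(days) {
  if (!length(days))
    return(data.table::data.table(start_day = integer(), end_day = integer()))
  days <- sort(unique(as.integer(days)))
  brk <- which(diff(days) > 1L)
  starts <- days[c(1L, brk + 1L)]
  ends <- days[c(brk, length(days))]
  data.table::data.table(start_day = starts, end_day = ends)
}

# Expand interval rows to the covered integer days.
runs_to_days <- function(start, end) {
  if (!length(start)) return(integer())
  unlist(Map(seq.int, as.integer(start), as.integer(end)), use.names = FALSE)
}

# Statistic dispatcher for assigned durations.
duration_stat_fun <- function(name) {
  switch(name,
         median = stats::median,
         mean = mean,
         stop("unsupported duration statistic: ", name))
}
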