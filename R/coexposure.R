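# Co-exposure interval algebra: pairwise overlap of treatment episodes,
# fixed-dose combination pass-through, higher-order combination discovery
# by fixed-point intersection, and the final gap-free co-exposure episode.
#
# All intervals are closed on both ends at day resolution, so two periods
# overlap iff max(starts) <= min(ends) and the overlap spans
# min(ends) - max(starts) + 1 days.

#' Do two closed day intervals share at least one day?
#'
#' @param a,b Length-2 numeric vectors `c(start, end)` with `start <= end`.
#' @return `TRUE` iff the intervals share at least one day; adjacent
#'   intervals (e.g. `[0,4]` and `[5,9]`) do not overlap.
#' @export
check_overlap <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L || anyNA(c(a, b)) ||
      a[1] > a[2] || b[1] > b[2])
    stop("intervals must be c(start, end) with start <= end")
  max(a[1], b[1]) <= min(a[2], b[2])
}

# Empty period table with the canonical columns.
empty_periods <- function(with_patient = FALSE) {
  dt <- data.table::data.table(agent_set = character(),
                               start_day = integer(), end_day = integer(),
                               n_days = integer(), n_agents = integer())
  if (with_patient) dt[, patient_id := character()]
  dt
}

finalize_periods <- function(dt) {
  if (!nrow(dt)) return(empty_periods())
  dt[, n_days := interval_days(start_day, end_day)]
  dt[, n_agents := n_agents(agent_set)]
  data.table::setorder(dt, agent_set, start_day)
  dt[]
}

#' Co-exposure periods between two drugs' treatment episodes
#'
#' Intersects every pair of episodes of two medication products: each
#' overlapping episode pair yields one co-exposure period
#' `[max(starts), min(ends)]` labelled with the union of the two products'
#' agent sets; the total co-exposure duration is the sum of the
#' overlapping periods (episodes within one product are disjoint, so the
#' periods never double-count a day).
#'
#' @param episodes_a,episodes_b `data.table`s with `start_day`, `end_day`
#'   columns; each internally disjoint and sorted.
#' @param agents_a,agents_b Character vectors of the agents contained in
#'   each product (a single code for a plain drug, the component set for a
#'   fixed-dose combination).
#' @return List with `periods`
#'   (`data.table(agent_set, start_day, end_day, n_days, n_agents)`) and
#'   `total_days`.
#' @export
pairwise_co_exposure <- function(episodes_a, episodes_b,
                                 agents_a = "A", agents_b = "B") {
  set_key <- agent_key(c(agents_a, agents_b))
  if (length(agents_from_key(set_key)) < 2L)
    stop("the two products must together contain at least two agents")
  na <- nrow(episodes_a); nb <- nrow(episodes_b)
  if (na == 0L || nb == 0L)
    return(list(periods = empty_periods(), total_days = 0L))
  starts <- integer(); ends <- integer()
  for (i in seq_len(na)) {
    s <- pmax(episodes_a$start_day[i], episodes_b$start_day)
    e <- pmin(episodes_a$end_day[i], episodes_b$end_day)
    keep <- s <= e
    starts <- c(starts, s[keep]); ends <- c(ends, e[keep])
  }
  if (!length(starts))
    return(list(periods = empty_periods(), total_days = 0L))
  periods <- finalize_periods(data.table::data.table(
    agent_set = set_key, start_day = as.integer(starts),
    end_day = as.integer(ends)))
  list(periods = periods, total_days = sum(periods$n_days))
}

#' Fixed-dose combination episodes as co-exposure periods
#'
#' A fixed-dose combination product delivers all of its component agents
#' for the whole of each of its treatment episodes, so its episodes are
#' emitted directly as co-exposure periods labelled with the component
#' set — no overlap computation is involved in creating them.
#'
#' @param episodes `data.table(start_day, end_day, ...)` treatment episodes
#'   of one fixed-dose product.
#' @param components Character vector (length >= 2) of component agents.
#' @return `data.table(agent_set, start_day, end_day, n_days, n_agents)`.
#' @export
expand_fixed_dose <- function(episodes, components) {
  if (length(unique(components)) < 2L)
    stop("a fixed-dose combination must have at least two components")
  if (nrow(episodes) == 0L) return(empty_periods())
  finalize_periods(data.table::data.table(
    agent_set = agent_key(components),
    start_day = as.integer(episodes$start_day),
    end_day = as.integer(episodes$end_day)))
}

# Drop periods whose interval is contained in another interval of the SAME
# agent set (keeps maximal intervals only; exact duplicates collapse).
prune_contained <- function(periods) {
  if (!nrow(periods)) return(periods)
  dt <- unique(periods[, .(agent_set, start_day, end_day)])
  data.table::setorder(dt, agent_set, start_day, -end_day)
  dt[, keep := {
    run_max <- cummax(c(-1L, utils::head(end_day, -1L)))
    end_day > run_max
  }, by = agent_set]
  out <- dt[keep == TRUE][, keep := NULL]
  finalize_periods(out)
}

#' Higher-order co-exposure periods by fixed-point intersection
#'
#' Starting from a patient's co-exposure periods (pair overlaps and
#' fixed-dose pass-through periods, each labelled with its agent set),
#' repeatedly intersects every two overlapping periods whose agent sets
#' differ, labelling the intersection with the union of the two sets,
#' until no new maximal period appears. The result is order-independent:
#' every emitted k-agent period (k >= 3) is the exact intersection of the
#' contributing products' episodes.
#'
#' @param periods `data.table(agent_set, start_day, end_day, ...)` — all
#'   co-exposure periods of one patient.
#' @return `data.table` of derived periods with `n_agents >= 3`, maximal
#'   per agent set.
#' @export
find_overlaps <- function(periods) {
  if (!nrow(periods)) return(empty_periods())
  pool <- prune_contained(data.table::as.data.table(periods))
  input_keys <- paste(pool$agent_set, pool$start_day, pool$end_day)
  repeat {
    m <- nrow(pool)
    if (m < 2L) break
    cand_set <- character(); cand_s <- integer(); cand_e <- integer()
    for (i in 1:(m - 1L)) {
      js <- (i + 1L):m
      s <- pmax(pool$start_day[i], pool$start_day[js])
      e <- pmin(pool$end_day[i], pool$end_day[js])
      ok <- s <= e & pool$agent_set[js] != pool$agent_set[i]
      if (!any(ok)) next
      uset <- vapply(pool$agent_set[js][ok], function(k)
        agent_key(c(agents_from_key(pool$agent_set[i]), agents_from_key(k))),
        character(1), USE.NAMES = FALSE)
      cand_set <- c(cand_set, uset)
      cand_s <- c(cand_s, s[ok]); cand_e <- c(cand_e, e[ok])
    }
    if (!length(cand_set)) break
    merged <- prune_contained(data.table::rbindlist(list(
      pool[, .(agent_set, start_day, end_day)],
      data.table::data.table(agent_set = cand_set, start_day = cand_s,
                             end_day = cand_e)), use.names = TRUE,
      fill = TRUE))
    if (nrow(merged) == nrow(pool)) break
    pool <- merged
  }
  out <- pool[!(paste(agent_set, start_day, end_day) %in% input_keys)]
  out <- out[n_agents(agent_set) >= 3L]
  finalize_periods(out)
}

#' Final gap-free co-exposure episodes for one patient
#'
#' Projects all of a patient's co-exposure periods (any agent set) onto
#' the day grid and merges intervals that overlap or are exactly adjacent
#' (a redemption pattern with contiguous coverage has no gap); a gap of
#' one or more uncovered days always separates episodes. No carry-over is
#' applied at this step.
#'
#' @param periods `data.table(start_day, end_day, ...)` co-exposure
#'   periods of one patient.
#' @return `data.table(episode_index, start_day, end_day, total_days)`.
#' @export
build_final_episode <- function(periods) {
  if (nrow(periods) == 0L)
    return(data.table::data.table(episode_index = integer(),
                                  start_day = integer(), end_day = integer(),
                                  total_days = integer()))
  dt <- data.table::as.data.table(periods)[, .(start_day, end_day)]
  data.table::setorder(dt, start_day, end_day)
  starts <- integer(); ends <- integer()
  cur_s <- dt$start_day[1L]; cur_e <- dt$end_day[1L]
  if (nrow(dt) > 1L) for (i in 2:nrow(dt)) {
    if (dt$start_day[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, dt$end_day[i])
    } else {
      starts <- c(starts, cur_s); ends <- c(ends, cur_e)
      cur_s <- dt$start_day[i]; cur_e <- dt$end_day[i]
    }
  }
  starts <- c(starts, cur_s); ends <- c(ends, cur_e)
  data.table::data.table(episode_index = seq_along(starts),
                         start_day = as.integer(starts),
                         end_day = as.integer(ends),
                         total_days = interval_days(starts, ends))
}

# Combination-class ATC prefixes (products containing >= 2 agents) used to
# warn when a likely FDC code has no component mapping.
FDC_CLASS_PREFIXES <- c("C02L", "C02N", "C03E", "C07B", "C07C", "C07D",
                        "C07F", "C08G", "C09B", "C09D", "C10B")

is_combination_atc <- function(atc) {
  Reduce(`|`, lapply(FDC_CLASS_PREFIXES, function(p) startsWith(atc, p)),
         accumulate = FALSE)
}

#' Compute all co-exposure periods and final episodes for a cohort
#'
#' Drives the full overlap algebra over per-drug treatment episodes: each
#' medication product carries its agent set (the code itself for a plain
#' drug, the component set for a fixed-dose combination found in
#' `fdc_map`); fixed-dose products' episodes pass through directly as
#' co-exposure periods; every product pair is intersected with
#' [pairwise_co_exposure()]; higher-order combinations are closed with
#' [find_overlaps()]; and [build_final_episode()] merges everything into
#' per-patient gap-free episodes.
#'
#' @param episodes `data.table(patient_id, atc, episode_index, start_day,
#'   end_day, ...)` as returned by [build_all_episodes()].
#' @param fdc_map Named list mapping fixed-dose ATC codes to their
#'   component agent vectors; `NULL` for none. A code in a known ATC
#'   combination class that is absent from the map is treated as a single
#'   agent, with a warning.
#' @param count_fdc_alone If `FALSE`, a fixed-dose product with no other
#'   concurrent medication product does not count as co-exposure: its
#'   pass-through periods are excluded (overlaps with other products still
#'   count).
#'
#' @return List with `periods` (`data.table(patient_id, agent_set,
#'   n_agents, start_day, end_day, n_days)`, maximal per agent set) and
#'   `final_episodes` (`data.table(patient_id, episode_index, start_day,
#'   end_day, total_days)`).
#' @export
compute_coexposure <- function(episodes, fdc_map = NULL,
                               count_fdc_alone = TRUE) {
  episodes <- data.table::as.data.table(episodes)
  unmapped <- unique(episodes$atc[is_combination_atc(episodes$atc) &
                                    !(episodes$atc %in% names(fdc_map))])
  if (length(unmapped))
    warning("combination-class ATC code(s) without a component map, ",
            "treated as single agents: ", paste(unmapped, collapse = ", "),
            call. = FALSE)

  per_patient <- function(pid, eps) {
    prods <- unique(eps$atc)
    agents <- lapply(prods, function(a)
      if (a %in% names(fdc_map)) as.character(fdc_map[[a]]) else a)
    names(agents) <- prods
    ep_by <- split(eps[, .(start_day, end_day)], eps$atc)[prods]

    base <- list()
    for (a in prods) {
      if (length(unique(agents[[a]])) >= 2L)
        base[[length(base) + 1L]] <- expand_fixed_dose(ep_by[[a]],
                                                       agents[[a]])
    }
    n_fdc_alone <- length(base)
    if (length(prods) > 1L) {
      for (i in 1:(length(prods) - 1L)) for (j in (i + 1L):length(prods)) {
        u <- unique(c(agents[[i]], agents[[j]]))
        if (length(u) < 2L) next
        pr <- pairwise_co_exposure(ep_by[[i]], ep_by[[j]],
                                   agents[[i]], agents[[j]])
        if (nrow(pr$periods))
          base[[length(base) + 1L]] <- pr$periods
      }
    }
    if (!length(base)) return(NULL)
    base_dt <- prune_contained(data.table::rbindlist(base))
    higher <- find_overlaps(base_dt)
    all_p <- prune_contained(data.table::rbindlist(list(base_dt, higher),
                                                   use.names = TRUE))
    if (!count_fdc_alone && n_fdc_alone > 0L) {
      # keep only days where >= 2 distinct products contribute: drop the
      # portions of FDC pass-through periods not overlapping any other
      # product's episodes
      fdc_codes <- prods[vapply(prods, function(a)
        length(unique(agents[[a]])) >= 2L, logical(1))]
      other_days <- function(excl) {
        unlist(lapply(setdiff(prods, excl), function(a)
          runs_to_days(ep_by[[a]]$start_day, ep_by[[a]]$end_day)),
          use.names = FALSE)
      }
      kept <- list()
      for (r in seq_len(nrow(all_p))) {
        row <- all_p[r]
        src_fdc <- fdc_codes[vapply(fdc_codes, function(a)
          all(agents[[a]] %in% agents_from_key(row$agent_set)), logical(1))]
        if (length(src_fdc) == 1L &&
            setequal(agents_from_key(row$agent_set), agents[[src_fdc]])) {
          od <- intersect(runs_to_days(row$start_day, row$end_day),
                          other_days(src_fdc))
          runs <- runs_from_days(od)
          if (nrow(runs)) {
            runs[, agent_set := row$agent_set]
            kept[[length(kept) + 1L]] <- runs
          }
        } else {
          kept[[length(kept) + 1L]] <- row[, .(start_day, end_day, agent_set)]
        }
      }
      all_p <- if (length(kept))
        prune_contained(data.table::rbindlist(kept, use.names = TRUE))
      else empty_periods()
    }
    if (!nrow(all_p)) return(NULL)
    all_p[, patient_id := pid]
    all_p
  }

  pids <- unique(episodes$patient_id)
  res <- lapply(pids, function(pid)
    per_patient(pid, episodes[patient_id == pid]))
  periods <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))],
                                   use.names = TRUE)
  if (!nrow(periods)) {
    periods <- empty_periods(with_patient = TRUE)
    finals <- data.table::data.table(patient_id = character(),
                                     episode_index = integer(),
                                     start_day = integer(),
                                     end_day = integer(),
                                     total_days = integer())
    return(list(periods = periods, final_episodes = finals))
  }
  data.table::setcolorder(periods, c("patient_id", "agent_set", "n_agents",
                                     "start_day", "end_day", "n_days"))
  finals <- periods[, build_final_episode(.SD), by = patient_id]
  data.table::setorder(periods, patient_id, agent_set, start_day)
  data.table::setorder(finals, patient_id, start_day)
  list(periods = periods[], final_episodes = finals[])
}
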