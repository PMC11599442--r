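# Sessa Empirical Estimator (SEE): data-driven assignment of prescription
# supply durations from the empirical distribution of refill waiting times.
#
# The estimator (i) computes waiting times between consecutive redemptions
# of the same drug by the same patient, pooled across patients per ATC
# code, (ii) discards waiting times above a trim percentile (presumed
# non-persistence gaps rather than supply), (iii) clusters the retained
# waiting times in one dimension, choosing the number of clusters by mean
# silhouette, and (iv) assigns each redemption the within-cluster median
# (or mean) of the cluster its observed waiting time falls into; the final
# redemption of a sequence, and any waiting time beyond the trim bound,
# receive the fallback duration (the statistic over all retained waiting
# times). Clustering is deterministic: k-means is initialised from evenly
# spaced quantiles with no random restarts, so repeated fits on the same
# data give identical durations.

#' Refill waiting times for one drug
#'
#' Computes the day gaps between consecutive redemptions of the same ATC
#' code by the same patient, pooled across patients. Patients with a single
#' redemption contribute nothing. Same-day duplicates must already have
#' been collapsed (see [read_register()]), so all waiting times are >= 1.
#'
#' @param records `data.table` with columns `patient_id` and `day`
#'   (day-index redemptions of a single ATC code), in any order.
#' @return Integer vector of waiting times in days.
#' @export
compute_waiting_times <- function(records) {
  if (nrow(records) == 0L) return(integer())
  dt <- data.table::as.data.table(records)[, .(patient_id, day)]
  data.table::setorder(dt, patient_id, day)
  wt <- dt[, if (.N > 1L) .(wt = diff(day)) else NULL, by = patient_id]$wt
  as.integer(if (is.null(wt)) integer() else wt)
}

# Exact mean silhouette width for a 1-D clustering without forming a
# distance matrix. For point i: a(i) = mean distance to its own cluster
# (excluding itself), b(i) = min over other clusters of the mean distance;
# s(i) = (b - a) / max(a, b), with s(i) = 0 for singleton clusters.
# Sums of |x - v| over a sorted vector v come from prefix sums, giving
# O(n k log n) overall.
silhouette_1d <- function(x, cluster) {
  ks <- sort(unique(cluster))
  n <- length(x)
  sorted <- lapply(ks, function(k) sort(x[cluster == k]))
  csums <- lapply(sorted, cumsum)
  sum_abs <- function(ci, q) {
    v <- sorted[[ci]]; cs <- csums[[ci]]; m <- length(v)
    pos <- findInterval(q, v)
    below <- ifelse(pos > 0L, cs[pmax(pos, 1L)], 0)
    below[pos == 0L] <- 0
    q * pos - below + (cs[m] - below) - q * (m - pos)
  }
  sizes <- vapply(sorted, length, integer(1))
  s <- numeric(n)
  for (ci in seq_along(ks)) {
    idx <- which(cluster == ks[ci])
    if (sizes[ci] <= 1L) { s[idx] <- 0; next }
    q <- x[idx]
    a <- sum_abs(ci, q) / (sizes[ci] - 1L)
    b <- rep(Inf, length(idx))
    for (cj in seq_along(ks)) {
      if (cj == ci) next
      b <- pmin(b, sum_abs(cj, q) / sizes[cj])
    }
    s[idx] <- (b - a) / pmax(a, b)
    s[idx][!is.finite(s[idx])] <- 0
  }
  mean(s)
}

# Deterministic 1-D k-means: centers initialised at evenly spaced quantiles
# of the data, Hartigan-Wong refinement, no random restarts. Returns NULL
# when k is infeasible for these data.
kmeans_1d <- function(x, k, iter_max = 100L) {
  ux <- unique(x)
  if (length(ux) < k) return(NULL)
  centers <- unname(stats::quantile(x, probs = (2 * seq_len(k) - 1) / (2 * k),
                                    type = 7))
  centers <- unique(centers)
  if (length(centers) < k) {
    # quantile collisions under heavy ties: fall back to evenly spaced
    # quantiles of the distinct values
    centers <- unname(stats::quantile(sort(ux),
                                      probs = (2 * seq_len(k) - 1) / (2 * k),
                                      type = 1))
    centers <- unique(centers)
    if (length(centers) < k) return(NULL)
  }
  tryCatch(
    stats::kmeans(x, centers = matrix(sort(centers), ncol = 1),
                  iter.max = iter_max),
    error = function(e) NULL
  )
}

#' Fit a duration-assignment model from refill waiting times
#'
#' Trims the waiting-time distribution at `trim_percentile`, clusters the
#' retained values (k chosen within `k_range` by maximum mean silhouette;
#' k = 1 when fewer than two distinct values remain), and assigns each
#' cluster a duration equal to the configured statistic of its members,
#' rounded to a whole day (at least 1). Cluster boundaries are midpoints
#' between adjacent cluster extremes, so every waiting time in
#' `(0, trim_bound]` maps to exactly one cluster. The fallback duration is
#' the statistic over all retained waiting times.
#'
#' @param waiting_times Integer vector of waiting times in days (see
#'   [compute_waiting_times()]).
#' @param trim_percentile Fraction of the distribution retained; values
#'   strictly above this empirical quantile (linear interpolation, type 7)
#'   are discarded.
#' @param k_range Candidate cluster counts.
#' @param duration_statistic `"median"` or `"mean"`.
#' @param default_duration_days Fallback when `waiting_times` is empty.
#' @param atc Optional ATC code stored in the model.
#'
#' @return An object of class `see_model`: list with `atc`,
#'   `trim_bound_days`, `clusters` (`data.table(cluster_id, lower_bound_days,
#'   upper_bound_days, assigned_duration_days, n, center)`),
#'   `fallback_duration_days`, `k`, `silhouette`, `n_waiting_times`,
#'   `n_retained`.
#' @export
fit_see <- function(waiting_times,
                    trim_percentile = 0.8,
                    k_range = 2:10,
                    duration_statistic = c("median", "mean"),
                    default_duration_days = 30L,
                    atc = NA_character_) {
  duration_statistic <- match.arg(duration_statistic)
  stat <- duration_stat_fun(duration_statistic)
  stopifnot(trim_percentile > 0, trim_percentile <= 1)
  wt <- as.numeric(waiting_times)
  wt <- wt[!is.na(wt)]
  if (any(wt < 1)) stop("waiting times must be >= 1 day")

  empty_clusters <- data.table::data.table(
    cluster_id = integer(), lower_bound_days = numeric(),
    upper_bound_days = numeric(), assigned_duration_days = integer(),
    n = integer(), center = numeric())

  if (!length(wt)) {
    warning("no waiting times available for ", atc,
            "; using default duration ", default_duration_days, " days",
            call. = FALSE)
    return(structure(list(
      atc = atc, trim_bound_days = NA_real_, clusters = empty_clusters,
      fallback_duration_days = as.integer(default_duration_days),
      k = 0L, silhouette = NA_real_, n_waiting_times = 0L, n_retained = 0L,
      trim_percentile = trim_percentile,
      duration_statistic = duration_statistic), class = "see_model"))
  }

  trim_bound <- unname(stats::quantile(wt, trim_percentile, type = 7))
  kept <- wt[wt <= trim_bound]

  dur_int <- function(v) max(1L, as.integer(round(stat(v))))
  fallback <- dur_int(kept)

  if (length(unique(kept)) < 2L) {
    clusters <- data.table::data.table(
      cluster_id = 1L, lower_bound_days = 0,
      upper_bound_days = trim_bound,
      assigned_duration_days = dur_int(kept),
      n = length(kept), center = mean(kept))
    k_best <- 1L; sil_best <- NA_real_
  } else {
    fits <- list(); sils <- numeric()
    for (k in sort(unique(k_range))) {
      km <- kmeans_1d(kept, k)
      if (is.null(km)) next
      fits[[as.character(k)]] <- km
      sils[as.character(k)] <- silhouette_1d(kept, km$cluster)
    }
    if (!length(fits)) {
      # every candidate k infeasible (e.g. k_range beyond distinct values)
      clusters <- data.table::data.table(
        cluster_id = 1L, lower_bound_days = 0,
        upper_bound_days = trim_bound,
        assigned_duration_days = dur_int(kept),
        n = length(kept), center = mean(kept))
      k_best <- 1L; sil_best <- NA_real_
    } else {
      pick <- names(sils)[which.max(sils)]  # ties: first, i.e. smallest k
      km <- fits[[pick]]
      k_best <- as.integer(pick); sil_best <- unname(sils[pick])
      ord <- order(km$centers[, 1])
      clusters <- data.table::rbindlist(lapply(seq_along(ord), function(i) {
        members <- kept[km$cluster == ord[i]]
        data.table::data.table(
          cluster_id = i,
          lo_ext = min(members), hi_ext = max(members),
          assigned_duration_days = dur_int(members),
          n = length(members), center = mean(members))
      }))
      # boundaries: midpoints between adjacent cluster extremes
      mids <- (clusters$hi_ext[-nrow(clusters)] + clusters$lo_ext[-1L]) / 2
      clusters[, lower_bound_days := c(0, mids)]
      clusters[, upper_bound_days := c(mids, trim_bound)]
      clusters[, c("lo_ext", "hi_ext") := NULL]
      data.table::setcolorder(clusters, c("cluster_id", "lower_bound_days",
                                          "upper_bound_days",
                                          "assigned_duration_days",
                                          "n", "center"))
    }
  }

  structure(list(
    atc = atc,
    trim_bound_days = trim_bound,
    clusters = clusters,
    fallback_duration_days = fallback,
    k = k_best,
    silhouette = sil_best,
    n_waiting_times = length(wt),
    n_retained = length(kept),
    trim_percentile = trim_percentile,
    duration_statistic = duration_statistic
  ), class = "see_model")
}

#' @export
print.see_model <- function(x, ...) {
  cat(sprintf("SEE model for %s: %d waiting times, %d retained (trim %.2f -> <= %.1f d)\n",
              x$atc, x$n_waiting_times, x$n_retained, x$trim_percentile,
              x$trim_bound_days))
  cat(sprintf("  k = %d cluster(s), fallback duration %d d\n",
              x$k, x$fallback_duration_days))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

# Map waiting times to cluster durations under the (lower, upper] rule.
see_duration_for <- function(model, wt) {
  out <- rep(model$fallback_duration_days, length(wt))
  if (nrow(model$clusters) && !is.na(model$trim_bound_days)) {
    ok <- wt <= model$trim_bound_days
    if (any(ok)) {
      idx <- findInterval(wt[ok], model$clusters$lower_bound_days,
                          left.open = TRUE)
      idx[idx < 1L] <- 1L
      out[ok] <- model$clusters$assigned_duration_days[idx]
    }
  }
  as.integer(out)
}

#' Assign supply durations to redemptions, producing medication events
#'
#' For each redemption except a patient's last, the event duration is the
#' assigned duration of the cluster containing the waiting time to the next
#' redemption; waiting times beyond the trim bound, and the final (or only)
#' redemption of each patient, receive the fallback duration. Events start
#' on the redemption day; intervals are closed, so an event of duration
#' `d` starting on day `t` covers days `t .. t + d - 1`.
#'
#' @param records `data.table(patient_id, day)` redemptions of one ATC code.
#' @param model A fitted [fit_see()] model for that code.
#' @return `data.table(patient_id, atc, start_day, duration_days, end_day)`
#'   with one row per redemption.
#' @export
assign_durations <- function(records, model) {
  if (!inherits(model, "see_model"))
    stop("no fitted SEE model supplied",
         if (!is.null(model$atc)) paste0(" for ", model$atc) else "")
  dt <- data.table::as.data.table(records)[, .(patient_id, day)]
  if (nrow(dt) == 0L)
    return(data.table::data.table(patient_id = character(),
                                  atc = character(), start_day = integer(),
                                  duration_days = integer(),
                                  end_day = integer()))
  data.table::setorder(dt, patient_id, day)
  out <- dt[, {
    d <- rep(model$fallback_duration_days, .N)
    if (.N > 1L) d[-.N] <- see_duration_for(model, diff(day))
    .(start_day = day, duration_days = as.integer(d))
  }, by = patient_id]
  out[, atc := model$atc]
  out[, end_day := start_day + duration_days - 1L]
  data.table::setcolorder(out, c("patient_id", "atc", "start_day",
                                 "duration_days", "end_day"))
  out[]
}

#' Fit SEE models and assign durations for every drug in a register
#'
#' Convenience driver: splits day-indexed redemptions by ATC code, fits one
#' [fit_see()] model per code from the pooled waiting times, and applies
#' [assign_durations()].
#'
#' @param events `data.table(patient_id, atc, day)` as returned by
#'   [to_relative_days()].
#' @param config A [study_config()] supplying the SEE settings.
#' @return List with `models` (named list of `see_model` by ATC) and
#'   `events` (`data.table` of medication events for all drugs).
#' @export
fit_see_register <- function(events, config = study_config()) {
  atcs <- sort(unique(events$atc))
  models <- list()
  ev_list <- list()
  for (code in atcs) {
    sub <- events[atc == code]
    wt <- compute_waiting_times(sub)
    models[[code]] <- fit_see(
      wt, trim_percentile = config$trim_percentile,
      k_range = config$k_range,
      duration_statistic = config$duration_statistic,
      default_duration_days = config$default_duration_days, atc = code)
    ev_list[[code]] <- assign_durations(sub, models[[code]])
  }
  med_events <- data.table::rbindlist(ev_list)
  data.table::setorder(med_events, patient_id, atc, start_day)
  list(models = models, events = med_events[])
}

#' Serialise fitted SEE models to JSON
#'
#' @param models Named list of `see_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_see_models <- function(models, path) {
  payload <- lapply(models, function(m) list(
    atc = m$atc, trim_bound_days = m$trim_bound_days,
    trim_percentile = m$trim_percentile, k = m$k,
    fallback_duration_days = m$fallback_duration_days,
    clusters = m$clusters))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
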