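#' Read a prescription-redemption register from delimited text
#'
#' Parses one row per redeemed prescription (patient identifier, ATC code,
#' redemption date, optional pack quantity), rejects malformed rows with a
#' per-row report, collapses exact same-day duplicates of the same drug for
#' the same patient (the register grain the method consumes is one
#' redemption event; duplicates would double-count supply), and returns the
#' records sorted by patient and date.
#'
#' Rows with dates outside the registry window — from `washout_days` before
#' the enrollment window start to `followup_days` after its end — are
#' dropped and counted.
#'
#' @param path Path to a CSV/TSV file with a header.
#' @param config A [study_config()].
#' @param col_map Named list mapping the canonical column roles
#'   `patient_id`, `atc`, `date` (and optionally `quantity`) to the column
#'   names used in the file.
#' @param sep Field separator; `"auto"` lets `data.table::fread` sniff it.
#'
#' @return A `data.table` with columns `patient_id`, `atc`, `date` (class
#'   `Date`) and, when present, `quantity`; attributes `n_raw`, `n_dropped`
#'   and `n_deduplicated` record row accounting.
#' @export
read_register <- function(path, config = study_config(),
                          col_map = list(patient_id = "patient_id",
                                         atc = "atc", date = "date",
                                         quantity = "quantity"),
                          sep = "auto") {
  if (!file.exists(path)) stop("register file not found: ", path)
  dt <- data.table::fread(path, sep = sep, colClasses = "character",
                          header = TRUE)
  if (nrow(dt) == 0L) stop("register file is empty: ", path)
  need <- c("patient_id", "atc", "date")
  miss <- need[!vapply(need, function(r) col_map[[r]] %in% names(dt), logical(1))]
  if (length(miss))
    stop("register is missing required column(s): ",
         paste(unlist(col_map[miss]), collapse = ", "))
  out <- data.table::data.table(
    patient_id = dt[[col_map$patient_id]],
    atc = dt[[col_map$atc]],
    date = as.Date(dt[[col_map$date]], format = "%Y-%m-%d")
  )
  has_qty <- !is.null(col_map$quantity) && col_map$quantity %in% names(dt)
  if (has_qty) out[, quantity := suppressWarnings(
    as.integer(dt[[col_map$quantity]]))]

  n_raw <- nrow(out)
  bad_date <- which(is.na(out$date))
  bad_atc <- which(is.na(out$atc) | out$atc == "")
  bad <- sort(unique(c(bad_date, bad_atc)))
  if (length(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    length(bad),
                    paste(utils::head(bad + 1L, 20L), collapse = ", ")),
            call. = FALSE)
    out <- out[-bad]
  }
  if (nrow(out) == 0L) stop("no valid rows in register: ", path)

  win_lo <- config$study_window[1] - config$washout_days
  win_hi <- config$study_window[2] + config$followup_days
  in_win <- out$date >= win_lo & out$date <= win_hi
  n_window_dropped <- sum(!in_win)
  out <- out[in_win]
  if (nrow(out) == 0L)
    stop("no register rows fall inside the registry window ",
         win_lo, " .. ", win_hi)

  before <- nrow(out)
  out <- unique(out, by = c("patient_id", "atc", "date"))
  data.table::setorder(out, patient_id, date, atc)
  data.table::setattr(out, "n_raw", n_raw)
  data.table::setattr(out, "n_dropped", length(bad) + n_window_dropped)
  data.table::setattr(out, "n_deduplicated", before - nrow(out))
  out[]
}

#' Write prescription records back to delimited text
#'
#' Emits the deduplicated, sorted register in a fixed dialect (comma
#' separated, ISO-8601 dates), so that `write_register(read_register(f))`
#' round-trips byte-identically.
#'
#' @param records A records `data.table` as returned by [read_register()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_register <- function(records, path) {
  out <- data.table::copy(records)
  data.table::setorder(out, patient_id, date, atc)
  out[, date := format(date, "%Y-%m-%d")]
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Convert calendar redemptions to follow-up day indices
#'
#' Maps each record to an integer day index relative to the patient's index
#' date (day 0 = the index date). Records beyond the end of follow-up are
#' dropped and counted; a record before its patient's index date is an
#' error, since cohort construction should have excluded it.
#'
#' @param records Records `data.table` (`patient_id`, `atc`, `date`).
#' @param index_dates `data.table` with columns `patient_id`, `index_date`,
#'   one row per patient (see [identify_new_users()]). Patients absent from
#'   `index_dates` are dropped.
#' @param config A [study_config()]; supplies `followup_days`.
#'
#' @return `data.table(patient_id, atc, day)` sorted by patient, day, atc,
#'   with attribute `n_dropped_post_followup`.
#' @export
to_relative_days <- function(records, index_dates, config = study_config()) {
  stopifnot(all(c("patient_id", "index_date") %in% names(index_dates)))
  if (anyDuplicated(index_dates$patient_id))
    stop("index_dates must have exactly one row per patient")
  ev <- merge(records, index_dates[, .(patient_id, index_date)],
              by = "patient_id")
  ev[, day := as.integer(date - index_date)]
  if (any(ev$day < 0L)) {
    bad <- ev[day < 0L][1L]
    stop(sprintf("record before index date (patient %s, %s < %s)",
                 bad$patient_id, bad$date, bad$index_date))
  }
  n_post <- sum(ev$day >= config$followup_days)
  ev <- ev[day < config$followup_days,
           .(patient_id, atc, day)]
  data.table::setorder(ev, patient_id, day, atc)
  data.table::setattr(ev, "n_dropped_post_followup", n_post)
  ev[]
}
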