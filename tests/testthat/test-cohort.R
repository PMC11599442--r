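cfg <- study_config()

test_that("washout identifies new users at the day level", {
  rec <- data.table(
    patient_id = c("P1", "P1",            # 273-day gap: excluded
                   "P2",                  # single redemption: new user
                   "P3", "P3"),           # exactly 365 days: included
    atc = "C03AB01",
    date = as.Date(c("1995-06-01", "1996-03-01",
                     "1996-07-01",
                     "1995-07-02", "1996-07-01")))
  idx <- identify_new_users(rec, cfg, registry_start = as.Date("1995-01-01"))
  expect_false("P1" %in% idx$patient_id)
  expect_equal(idx[patient_id == "P2", index_date], as.Date("1996-07-01"))
  expect_equal(idx[patient_id == "P3", index_date], as.Date("1996-07-01"))

  expect_error(identify_new_users(rec, cfg,
                                  registry_start = as.Date("1995-06-01")),
               "washout")
})

test_that("age threshold requires reaching 65 during the study window", {
  rec <- data.table(patient_id = c("P1", "P2"), atc = "C03AB01",
                    date = as.Date("2010-06-01"))
  bd <- data.table(patient_id = c("P1", "P2"),
                   birthdate = as.Date(c("1950-01-01",   # 65 in 2015: in
                                         "1953-01-01"))) # 65 in 2018: out
  idx <- identify_new_users(rec, cfg, birthdates = bd,
                            registry_start = as.Date("1995-01-01"))
  expect_equal(idx$patient_id, "P1")
})

test_that("censoring truncates coverage the day before the censor day", {
  eps <- ep(c(0, 500))
  cz <- data.table(patient_id = "P1", censor_day = 400L, cause = "death")
  out <- apply_censoring(eps, cz, 730L)
  expect_equal(out[, c(start_day, end_day)], c(0L, 399L))

  # no censoring record: capped at day 729 only
  out2 <- apply_censoring(ep(c(0, 800)), NULL, 730L)
  expect_equal(out2$end_day, 729L)

  # censor day 0: the patient contributes nothing
  out3 <- apply_censoring(eps, data.table(patient_id = "P1",
                                          censor_day = 0L), 730L)
  expect_equal(nrow(out3), 0L)
})

test_that("stage clipping is exact and additive", {
  # reported days 170..200 = internal 169..199: 11 early + 20 late days
  p <- per(list(c("A", "B"), 169, 199), patient = "P1")
  st <- stage_split(p, early_end = 180L, followup_days = 730L)
  expect_equal(st[stage == "early", n_days], 11L)
  expect_equal(st[stage == "late", n_days], 20L)
  expect_equal(st[stage == "early", c(start_day, end_day)], c(169L, 179L))
  expect_equal(st$incident_stage, c("early", "early"))

  early_only <- stage_split(per(list(c("A", "B"), 0, 100), patient = "P1"))
  expect_equal(early_only$stage, "early")

  # a period starting on internal day 180 (reported day 181) is late-incident
  late <- stage_split(per(list(c("A", "B"), 180, 200), patient = "P1"))
  expect_equal(late$stage, "late")
  expect_equal(late$incident_stage, "late")

  # additivity over random periods
  set.seed(12)
  rnd <- data.table(patient_id = sprintf("P%d", 1:50),
                    agent_set = "A+B",
                    start_day = sample(0:700, 50))
  rnd[, end_day := pmin(start_day + sample(1:400, 50, replace = TRUE),
                        729L)]
  rnd[, n_days := end_day - start_day + 1L]
  st2 <- stage_split(rnd)
  sums <- st2[, .(clipped = sum(n_days)), by = patient_id]
  expect_equal(merge(sums, rnd, by = "patient_id")[, all(clipped == n_days)],
               TRUE)
})

test_that("combination tables rank, summarise and suppress correctly", {
  p <- rbindlist(list(
    per(list(c("A", "B"), 0, 9), patient = "P1"),
    per(list(c("A", "B"), 0, 19), patient = "P2"),
    per(list(c("A", "B"), 0, 29), patient = "P3"),
    per(list(c("A", "C"), 0, 9), patient = "P1"),
    per(list(c("A", "C"), 0, 9), patient = "P2"),
    per(list(c("A", "C"), 0, 9), patient = "P4")))
  st <- stage_split(p)

  tab <- summarize_combinations(st, "early", min_cell_size = 1L)
  ab <- tab[agent_set == "A+B"]
  expect_equal(ab$n_patients, 3L)
  expect_equal(ab[, c(median_days, q1_days, q3_days)], c(20, 15, 25))
  # equal n: deterministic lexicographic tie-break
  expect_equal(tab$agent_set, c("A+B", "A+C"))

  sup <- summarize_combinations(st, "early", min_cell_size = 5L)
  expect_true(all(is.na(sup$n_patients)))
  expect_true(all(sup$n_display == "<5"))

  none <- summarize_combinations(stage_split(p[0]), "late")
  expect_equal(nrow(none), 0L)
})

test_that("multiplicity is the largest concurrent agent set per patient", {
  p <- rbindlist(list(
    per(list(c("A", "B"), 0, 9), patient = "P1"),
    per(list(c("A", "B"), 0, 9), patient = "P2"),
    per(list(c("A", "B", "C"), 5, 9), patient = "P2"),
    per(list(c("A", "B", "C", "D"), 0, 9), patient = "P3")))
  mc <- multiplicity_counts(stage_split(p), "early", min_cell_size = 1L)
  expect_equal(mc[multiplicity == "2", n_patients], 1L)
  expect_equal(mc[multiplicity == "3", n_patients], 1L)
  expect_equal(mc[multiplicity == "4+", n_patients], 1L)
  expect_equal(sum(mc$pct), 100)
})

test_that("calendar timelines bin, rank and validate", {
  p <- rbindlist(lapply(sprintf("P%02d", 1:20), function(pid)
    per(list(c("A", "B"), 0, 9), patient = pid)))
  p2 <- rbindlist(lapply(sprintf("P%02d", 1:8), function(pid)
    per(list(c("A", "C"), 0, 9), patient = pid)))
  idx <- data.table(patient_id = sprintf("P%02d", 1:20),
                    index_date = as.Date(rep(c("1997-06-01", "2007-06-01"),
                                             each = 10)))
  tl <- timeline_top5(stage_split(rbindlist(list(p, p2))), idx)
  expect_equal(sort(unique(tl$period)), c("1996-2000", "2006-2010"))
  # A+B leads in both bins; A+C only passes the cell threshold in bin 1
  expect_equal(tl[period == "1996-2000" & stage == "early" & rank == 1,
                  agent_set], "A+B")
  expect_equal(tl[period == "1996-2000" & stage == "early" & rank == 2,
                  agent_set], "A+C")
  expect_false("A+C" %in% tl[period == "2006-2010", agent_set])

  expect_error(timeline_top5(stage_split(p), idx,
                             period_bins = list(c(1996L, 2000L))),
               "not covered")
  expect_error(timeline_top5(stage_split(p), idx,
                             period_bins = list(c(1996L, 2010L),
                                                c(2005L, 2018L))),
               "overlap")
})
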