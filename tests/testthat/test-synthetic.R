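test_that("generation is reproducible and seed-sensitive", {
  a <- generate_register(40, seed = 123)
  b <- generate_register(40, seed = 123)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c <- generate_register(40, seed = 124)
  expect_false(identical(a$records, c$records))
})

test_that("ground-truth coverage matches construction", {
  # single agent, clockwork refills: continuous coverage, no co-exposure
  mix1 <- list(list(spec = regimen_spec("A", durations = list(30L),
                                        jitter = 0L, refill_gap_prob = 0),
                    weight = 1))
  s1 <- generate_register(1, mix1, seed = 1, washout_violator_frac = 0,
                          post_followup_decoy_frac = 0)
  expect_equal(s1$truth[, .(start_day, end_day)],
               data.table(start_day = 0L, end_day = 729L))
  o1 <- day_level_oracle(s1$truth)
  expect_equal(o1$totals$total_days, 0L)

  # two agents, both covering days 0..179: 180 co-exposed days
  mix2 <- list(list(spec = regimen_spec(c("A", "B"), durations = list(90L),
                                        jitter = 0L, refill_gap_prob = 0,
                                        discontinue_day = 90L),
                    weight = 1))
  s2 <- generate_register(1, mix2, seed = 1, washout_violator_frac = 0,
                          post_followup_decoy_frac = 0)
  o2 <- day_level_oracle(s2$truth)
  expect_equal(o2$totals$total_days, 180L)
  expect_equal(o2$final_episodes[, c(start_day, end_day)], c(0L, 179L))
})

test_that("the day oracle intersects coverage literally", {
  cov <- rbindlist(list(ep(c(0, 9), atc = "A"), ep(c(5, 14), atc = "B")))
  o <- day_level_oracle(cov)
  expect_equal(o$final_episodes[, c(start_day, end_day)], c(5L, 9L))

  expect_equal(day_level_oracle(ep(c(0, 9)))$totals$total_days, 0L)

  # an FDC alone co-exposes its components for its whole coverage
  fdc <- day_level_oracle(ep(c(0, 29), atc = "C09BB04"),
                          fdc_map = list(C09BB04 = c("X", "Y")))
  expect_equal(fdc$final_episodes[, c(start_day, end_day)], c(0L, 29L))
  none <- day_level_oracle(ep(c(0, 29), atc = "C09BB04"),
                           fdc_map = list(C09BB04 = c("X", "Y")),
                           count_fdc_alone = FALSE)
  expect_equal(none$totals$total_days, 0L)
})

test_that("noiseless synthetic pipelines reproduce the truth exactly", {
  # jitter 0, no gaps, one pack size: SEE recovers the true duration and
  # the interval pipeline equals the truth-mode oracle patient by patient
  # drugs are not shared across regimens so each drug's pooled waiting
  # times are homogeneous and the estimator can match the truth exactly
  mix <- list(
    list(spec = regimen_spec(c("A", "B"), durations = list(28L),
                             jitter = 0L, refill_gap_prob = 0,
                             start_offsets = c(0L, 40L)), weight = 0.6),
    list(spec = regimen_spec(c("C", "D"), durations = list(84L),
                             jitter = 0L, refill_gap_prob = 0,
                             start_offsets = c(0L, 100L)), weight = 0.4))
  sim <- generate_register(50, mix, seed = 21, washout_violator_frac = 0,
                           post_followup_decoy_frac = 0)
  cfg <- study_config()
  see <- fit_see_register(sim$events, cfg)
  eps <- build_all_episodes(see$events, cfg$permissible_gap_days,
                            cfg$followup_days)
  co <- compute_coexposure(eps, sim$fdc_map)
  oracle <- day_level_oracle(sim$truth, sim$fdc_map)
  got <- co$final_episodes[, .(patient_id, start_day, end_day)]
  want <- oracle$final_episodes[, .(patient_id, start_day, end_day)]
  setorder(got, patient_id, start_day)
  setorder(want, patient_id, start_day)
  expect_equal(got, want)
})

test_that("accuracy scoring counts exact start/end matches per patient", {
  pf <- rbindlist(list(
    data.table(patient_id = sprintf("P%03d", 1:10), start_day = 0L,
               end_day = 99L)))
  acc <- evaluate_accuracy(pf, pf, pf$patient_id, sample_size = 10L,
                           seed = 1)
  expect_equal(acc$accuracy_pct, 100)

  worse <- copy(pf)[patient_id == "P003", end_day := 100L]
  acc2 <- evaluate_accuracy(worse, pf, pf$patient_id, sample_size = 10L,
                            seed = 1)
  expect_equal(acc2$accuracy_pct, 90)   # 9/10 correct
  expect_equal(acc2$discrepancies$patient_id, "P003")

  expect_warning(
    acc3 <- evaluate_accuracy(pf, pf, pf$patient_id, sample_size = 400L,
                              seed = 1),
    "evaluating all")
  expect_equal(acc3$n_evaluated, 10L)
  expect_error(evaluate_accuracy(pf, pf, character()), "no eligible")
})

test_that("combination oracle matches the interval algebra on free-dose patients", {
  set.seed(31)
  for (rep in 1:25) {
    agents <- LETTERS[1:sample(2:4, 1)]
    eps <- rbindlist(lapply(agents, function(a) {
      n <- sample(1:3, 1)
      starts <- sort(sample(seq(0, 600, by = 50), n))
      lens <- sample(30:150, n, replace = TRUE)
      data.table(patient_id = "P1", atc = a, episode_index = seq_len(n),
                 start_day = starts,
                 end_day = pmin(starts + lens, 729L), n_events = 1L)
    }))
    # keep each drug's episodes disjoint
    eps <- eps[, {
      keep <- rep(TRUE, .N); last_end <- -2L
      for (i in seq_len(.N)) {
        if (start_day[i] <= last_end + 1L) keep[i] <- FALSE
        else last_end <- end_day[i]
      }
      .SD[keep]
    }, by = .(patient_id, atc)]
    co <- compute_coexposure(eps)
    want <- oracle_combination_periods(eps)
    got <- co$periods[, .(patient_id, agent_set, start_day, end_day,
                          n_days)]
    setorder(got, patient_id, agent_set, start_day)
    expect_equal(got, want, info = sprintf("rep %d", rep))
  }
})
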