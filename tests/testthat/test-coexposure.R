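test_that("closed-interval overlap detection", {
  expect_true(check_overlap(c(0, 10), c(5, 15)))
  expect_false(check_overlap(c(0, 4), c(5, 9)))     # adjacent, no shared day
  expect_true(check_overlap(c(0, 10), c(10, 20)))   # share day 10 only
  expect_error(check_overlap(c(10, 0), c(0, 5)), "start <= end")
})

test_that("pairwise co-exposure sums the overlapping episode pairs", {
  a <- ep(c(0, 100))
  b <- ep(c(50, 150), c(200, 300), atc = "B")
  r <- pairwise_co_exposure(a, b, "A", "B")
  expect_equal(nrow(r$periods), 1L)
  expect_equal(r$periods[, c(start_day, end_day)], c(50L, 100L))
  expect_equal(r$total_days, 51L)  # |{50..100}|

  full <- pairwise_co_exposure(ep(c(0, 729)), ep(c(0, 729)), "A", "B")
  expect_equal(full$total_days, 730L)

  r2 <- pairwise_co_exposure(ep(c(0, 10), c(20, 30)), ep(c(5, 25)),
                             "A", "B")
  expect_equal(r2$periods[, .(start_day, end_day)],
               data.table(start_day = c(5L, 20L), end_day = c(10L, 25L)))
  expect_equal(r2$total_days, 12L)

  # symmetry
  r3 <- pairwise_co_exposure(ep(c(5, 25)), ep(c(0, 10), c(20, 30)),
                             "B", "A")
  expect_equal(r3$periods, r2$periods)
  expect_equal(nrow(pairwise_co_exposure(ep(c(0, 1))[0], ep(c(0, 1)),
                                         "A", "B")$periods), 0L)
  expect_error(pairwise_co_exposure(ep(c(0, 1)), ep(c(0, 1)), "A", "A"),
               "at least two agents")
})

test_that("fixed-dose episodes pass through with their component set", {
  p <- expand_fixed_dose(ep(c(0, 90), atc = "C09BB04"),
                         c("C09AA04", "C08CA01"))
  expect_equal(p$agent_set, agent_key(c("C08CA01", "C09AA04")))
  expect_equal(p[, c(start_day, end_day, n_days)], c(0L, 90L, 91L))
  expect_error(expand_fixed_dose(ep(c(0, 90)), "C09AA04"),
               "at least two components")
  expect_equal(nrow(expand_fixed_dose(ep(c(0, 1))[0], c("X", "Y"))), 0L)
})

test_that("agent sets merge into one canonical sorted set", {
  expect_equal(combine_pairs(list(c("A", "B"), c("B", "C"))),
               c("A", "B", "C"))
  expect_equal(combine_pairs(list(c("A", "B"), c("A", "B"))), c("A", "B"))
  expect_equal(combine_pairs(list(c("B", "A"))),
               combine_pairs(list(c("A", "B"))))
  expect_equal(combine_pairs(c("B+C", "A+B")), c("A", "B", "C"))
  expect_error(combine_pairs(list()), "at least one")
})

test_that("overlapping pair periods close into higher-order combinations", {
  pairs <- per(list(c("A", "B"), 10, 60),
               list(c("B", "C"), 40, 90),
               list(c("A", "C"), 40, 60))
  tri <- find_overlaps(pairs)
  expect_equal(nrow(tri), 1L)
  expect_equal(tri$agent_set, agent_key(c("A", "B", "C")))
  expect_equal(tri[, c(start_day, end_day)], c(40L, 60L))  # {40..60}

  none <- find_overlaps(per(list(c("A", "B"), 0, 10),
                            list(c("B", "C"), 50, 60)))
  expect_equal(nrow(none), 0L)
})

test_that("four agents covering the full window yield every combination", {
  eps <- rbindlist(lapply(c("A", "B", "C", "D"), function(a)
    ep(c(0, 729), atc = a)))
  co <- compute_coexposure(eps)
  expect_equal(nrow(co$periods), choose(4, 2) + choose(4, 3) + 1L)
  expect_true(all(co$periods$start_day == 0L & co$periods$end_day == 729L))
  expect_equal(sort(unique(co$periods$n_agents)), 2:4)
  expect_equal(co$final_episodes$total_days, 730L)
})

test_that("fixed-dose and free-dose episodes combine into 3-agent periods", {
  eps <- rbindlist(list(ep(c(0, 90), atc = "C09BB04"),
                        ep(c(50, 120), atc = "C03AB01")))
  co <- compute_coexposure(eps,
                           fdc_map = list(C09BB04 = c("C09AA04",
                                                      "C08CA01")))
  tri <- co$periods[n_agents == 3L]
  expect_equal(tri[, c(start_day, end_day)], c(50L, 90L))
  expect_equal(tri$agent_set,
               agent_key(c("C03AB01", "C08CA01", "C09AA04")))
  # the FDC alone is already co-exposure over [0,90]; the free-dose drug
  # adds no co-exposed days beyond day 90 (it is single coverage there)
  expect_equal(co$final_episodes[, c(start_day, end_day)], c(0L, 90L))

  # unmapped combination-class code: warned, treated as one agent
  expect_warning(
    co2 <- compute_coexposure(rbindlist(list(ep(c(0, 90), atc = "C09BB04"),
                                             ep(c(50, 120),
                                                atc = "C03AB01")))),
    "without a component map")
  expect_true(all(co2$periods$n_agents == 2L))
})

test_that("a single fixed-dose product can be excluded by configuration", {
  eps <- ep(c(0, 90), atc = "C09BB04")
  fdc <- list(C09BB04 = c("C09AA04", "C08CA01"))
  with_fdc <- compute_coexposure(eps, fdc, count_fdc_alone = TRUE)
  expect_equal(with_fdc$final_episodes$total_days, 91L)
  without <- compute_coexposure(eps, fdc, count_fdc_alone = FALSE)
  expect_equal(nrow(without$final_episodes), 0L)
})

test_that("final episodes merge adjacency but never bridge a 1-day gap", {
  f <- build_final_episode(per(list(c("A", "B"), 10, 50),
                               list(c("A", "C"), 40, 80),
                               list(c("B", "C"), 100, 120)))
  expect_equal(f[, .(start_day, end_day, total_days)],
               data.table(start_day = c(10L, 100L), end_day = c(80L, 120L),
                          total_days = c(71L, 21L)))
  expect_equal(sum(f$total_days), 92L)

  one <- build_final_episode(per(list(c("A", "B"), 5, 9)))
  expect_equal(one[, c(start_day, end_day)], c(5L, 9L))

  adj <- build_final_episode(per(list(c("A", "B"), 0, 10),
                                 list(c("A", "C"), 11, 20)))
  expect_equal(nrow(adj), 1L)  # day-adjacent coverage is contiguous

  gap <- build_final_episode(per(list(c("A", "B"), 0, 10),
                                 list(c("A", "C"), 12, 20)))
  expect_equal(nrow(gap), 2L)  # day 11 uncovered
  expect_equal(nrow(build_final_episode(per(list(c("A", "B"), 0, 1))[0])),
               0L)
})

test_that("containment and pair-total bounds hold on random registers", {
  set.seed(77)
  for (rep in 1:30) {
    agents <- LETTERS[1:sample(2:4, 1)]
    eps <- rbindlist(lapply(agents, function(a) {
      n <- sample(1:3, 1)
      starts <- sort(sample(0:600, n))
      ends <- pmin(starts + sample(20:120, n, replace = TRUE), 729L)
      # enforce disjoint episodes
      if (n > 1) for (i in 2:n) starts[i] <- max(starts[i], ends[i - 1] + 40L)
      keep <- starts <= 729L & starts <= ends
      data.table(patient_id = "P1", atc = a,
                 episode_index = seq_len(sum(keep)),
                 start_day = starts[keep], end_day = pmin(ends[keep], 729L),
                 n_events = 1L)
    }))
    co <- compute_coexposure(eps)
    pp <- co$periods
    if (!nrow(pp)) next
    # each k-agent period is contained in a period of every (k-1)-subset
    for (r in which(pp$n_agents >= 3L)) {
      s <- agents_from_key(pp$agent_set[r])
      for (drop in seq_along(s)) {
        sub <- agent_key(s[-drop])
        host <- pp[agent_set == sub & start_day <= pp$start_day[r] &
                     end_day >= pp$end_day[r]]
        expect_gte(nrow(host), 1L)
      }
    }
    # pair co-exposure total <= min of the two drugs' episode days
    totals <- eps[, .(days = sum(end_day - start_day + 1L)), by = atc]
    for (key in unique(pp[n_agents == 2L, agent_set])) {
      s <- agents_from_key(key)
      if (!all(s %in% totals$atc)) next
      expect_lte(pp[agent_set == key, sum(n_days)],
                 min(totals[atc %in% s, days]))
    }
  }
})

test_that("adding a prescription never decreases co-exposure totals", {
  set.seed(5)
  cfg <- study_config()
  base_ev <- data.table(
    patient_id = "P1",
    atc = rep(c("A", "B"), each = 4),
    start_day = c(0L, 30L, 60L, 200L, 10L, 40L, 300L, 340L),
    duration_days = 30L)
  for (rep in 1:20) {
    extra <- data.table(patient_id = "P1",
                        atc = sample(c("A", "B"), 1),
                        start_day = sample(0:700, 1),
                        duration_days = sample(c(10L, 30L, 84L), 1))
    tot <- function(evts) {
      eps <- build_all_episodes(evts, 30, 730L)
      sum(compute_coexposure(eps)$final_episodes$total_days)
    }
    expect_gte(tot(rbindlist(list(base_ev, extra))), tot(base_ev))
  }
})
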