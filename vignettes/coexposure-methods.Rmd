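---
title: "Assessing medication co-exposure from redemption registers: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing medication co-exposure from redemption registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexposr)
library(data.table)
```

## The problem

Prescription-redemption registers record *when* a prescription was filled,
not how long its supply lasted nor whether two drugs were taken
concurrently. For combination therapy — such as free-dose antihypertensive
regimens, where two or more separately dispensed agents are meant to be
taken together — the scientific quantity of interest is **co-exposure**:
the days on which a patient was simultaneously covered by two or more
distinct active agents. `coexposr` reconstructs those days from redemption
dates alone, with day-exact start and end dates per co-exposure episode,
and validates the reconstruction against an independent brute-force
enumeration.

## The day grid and interval conventions

All computation happens on an integer day grid. Day 0 is the patient's
index date (first qualifying redemption); follow-up covers days
`0 .. followup_days - 1` (730 covered days by default). Intervals are
closed at both ends: `[s, e]` covers `e - s + 1` days, two intervals
overlap iff `max(starts) <= min(ends)`, and the overlap spans
`min(ends) - max(starts) + 1` days. This convention matches day-count
language ("number of days of co-exposure") and makes the brute-force
day-enumeration oracle an exact arbiter: every interval statement can be
checked by listing days. Reported stage windows map onto the internal grid
as reported days 1–180 = internal days 0–179 (early stage) and 181–730 =
180–729 (late stage). Whether the index day is counted as day 0 or day 1
is a convention, not something register data can decide; it is declared
here once and used consistently, including by the oracle.

## Step 1a: supply durations from refill waiting times

Registers rarely carry reliable days-supplied fields, so durations are
estimated from behaviour: the **waiting time** between two consecutive
redemptions of the same drug by the same patient is, for adherent
stretches, the duration of the first pack. The Sessa Empirical Estimator
(SEE) operationalises this:

1. pool waiting times per drug across patients (per-patient distributions
   are too sparse for a population-level empirical estimator);
2. discard waiting times above the `trim_percentile` empirical quantile
   (default 0.8, linear-interpolation quantile) — the upper tail reflects
   non-persistence gaps, not supply;
3. cluster the retained values in one dimension (k-means over
   `k_range = 2..10`, k chosen by maximum mean silhouette; k = 1 when
   fewer than two distinct values remain). Clustering is deterministic:
   centres initialise at evenly spaced quantiles, no random restarts, so
   repeated fits give identical durations — a prerequisite for the
   accuracy audit to be reproducible;
4. each cluster's assigned duration is the within-cluster median (the
   `duration_statistic`), rounded to a whole day; cluster boundaries are
   midpoints between adjacent cluster extremes, so any waiting time in
   `(0, trim_bound]` maps to exactly one cluster.

Each redemption except a patient's last receives the duration of the
cluster containing its observed waiting time; waiting times beyond the
trim bound, and each patient's final redemption, receive the **fallback**
duration (the median of all retained waiting times). Assignment is
per-event rather than one duration per drug: the per-event rule uses the
information the register actually carries (this drug, this refill
rhythm), and one-duration-per-drug remains available by fitting with
`k_range = 1`. An empty waiting-time set (a drug nobody refilled) falls
back to `default_duration_days` (30) with a warning.

The mean silhouette is computed exactly in `O(n k log n)` from prefix
sums over the sorted cluster values rather than from an `n × n` distance
matrix; a unit test cross-checks it against `cluster::silhouette()` to
machine precision.

Two practical notes. First, the trim percentile encodes an assumption
about the data: roughly the top fifth of waiting times are gaps. Where a
drug's true pack-size mixture puts a genuine supply duration above the
0.8 quantile (e.g. a rarely dispensed large pack), that duration is
trimmed away and its events fall back to the overall median — the
estimator is deliberately conservative about long waiting times. Second,
fixed-dose combination products are fitted exactly like any other
product: their estimated duration *is* the co-exposure duration of their
components.

## Step 1b: treatment episodes

Per patient and drug, medication events merge into **treatment episodes**
under two rules:

* **Carry-over (same medication only).** A running coverage end `C` tracks
  supply: an event on day `t` with duration `d` inside an episode updates
  `C <- max(C, t - 1) + d`, so refilling early shifts the unused days
  forward instead of discarding them.
* **Permissible gap.** If the next redemption starts more than
  `permissible_gap_days` (default 30) after coverage ends — i.e.
  `t > C + gap + 1`, so a redemption the day after coverage ends is a
  0-day gap — the episode closes and a new one opens. The gap arithmetic
  is a declared convention; register days are integers and some
  convention must fix whether adjacency counts as a gap.

Coverage (not stored supply) is truncated at `followup_days - 1`, so total
episode days per patient-drug never exceed follow-up. Supply accumulates
without bound *within* an episode; it never crosses an episode boundary,
because a gap means the supply was exhausted before the next redemption.
The sequential algorithm is provably equivalent to pouring supply
day-by-day and splitting covered runs at gaps beyond the threshold; the
test suite checks that equivalence against an independently coded pouring
oracle on 200 randomized event sequences.

## Steps 2–3: overlap algebra

Co-exposure periods arise from three sources:

1. **Pairwise overlap.** For every pair of medication products, each
   overlapping pair of treatment episodes contributes the period
   `[max(starts), min(ends)]`, labelled with the union of the two
   products' agent sets. Episodes within one product are disjoint, so
   summing period lengths never double-counts a day.
2. **Fixed-dose pass-through.** A fixed-dose product's episodes are
   emitted directly as co-exposure periods of its component agents — no
   overlap computation creates them, because a single redemption of the
   product already certifies concurrent supply of all components. By
   default a fixed-dose product alone therefore counts as co-exposure
   (`count_fdc_alone = TRUE`); a switch restricts co-exposure to days
   covered by at least two distinct products, for analyses that define
   combination therapy at the product level.
3. **Higher-order closure.** `find_overlaps()` repeatedly intersects
   every two overlapping periods with different agent sets, labelling the
   intersection with the set union, until a fixed point; non-maximal
   intervals per agent set are pruned. The fixed point is
   order-independent — unlike an iterate-in-data-order formulation, the
   result does not depend on row order — and equals the exact k-way
   intersection of the member products' episodes, so every emitted
   k-agent period is contained in a period of each of its
   (k−1)-subsets.

The **final co-exposure episode** merges all of a patient's periods:
overlapping or exactly day-adjacent intervals join (on a day grid,
adjacency is continuity); one or more uncovered days always separate
episodes; no carry-over and no permissible gap apply at this step.

When one agent is covered both by a free-dose product and by a fixed-dose
product containing it, the product-level algebra can label an interval
with a smaller agent set than a per-agent day-coverage view would. Final
episodes — the validated quantity — are unaffected: a day is in a final
episode iff at least two distinct agents cover it, however labelled. The
per-set label equivalence is therefore asserted exactly on free-dose-only
patients, and final-episode equivalence on all patients including
fixed-dose users.

## Cohort design

* **New users.** A patient's index date is their first study-drug
  redemption (ATC prefix match) inside the enrollment window with no
  study-drug redemption in the washout window before it. The washout rule
  is `0 < index − prior < washout_days` (365): a redemption exactly 365
  days before the index does not exclude. Failing the washout excludes
  the patient (new-user design), not merely the candidate date. The
  register must reach back `washout_days` before the enrollment window,
  otherwise washout status is unknowable and the function refuses to
  guess.
* **Age.** When birthdates are supplied, eligibility requires reaching
  `age_threshold_years` (65) for at least one day during the study
  window, i.e. the 65th birthday falls on or before the window end.
* **Censoring.** A patient censored on day `c` (death, emigration)
  contributes coverage through day `c − 1`; intervals emptied by
  truncation vanish, and a censor day of 0 removes the patient.
* **Stages.** Each co-exposure period is clipped to the early
  (reported days 1–180) and late (181–730) windows; early + late clipped
  days always equal total days. A combination is *incident* in the stage
  containing its first co-exposed day; stage durations are the clipped
  day counts. This attribution is declared rather than inferable: it is
  consistent with early-stage upper quartiles bounded by the stage length.
* **Summaries.** Combination tables report distinct incident patients,
  their share of all patients with any co-exposed day in the stage (the
  denominator choice is a config option; the subpopulation-of-pairs
  alternative is also supported), and median (Q1–Q3) of per-patient
  clipped days, with quartiles by linear interpolation between order
  statistics (stated so tests can be exact). Ranking is by count
  descending with lexicographic tie-breaks. Multiplicity counts use each
  patient's largest concurrent agent set in the stage. Calendar timelines
  bin patients by index year (default four/three-year bins 1996–2018) and
  rank the top 5 incident combinations per bin and stage.
* **Disclosure control.** Any emitted count below `min_cell_size` (5) is
  masked as `<5` with numeric summaries withheld; rankings exclude
  suppressed rows entirely.

## The synthetic register and what it does (not) show

The generator emulates the register the method was designed for, with
known ground truth. Its defaults are the study conditions:

* first-line antihypertensive products (a thiazide-potassium product,
  amlodipine, enalapril, losartan, and the perindopril/amlodipine
  fixed-dose product C09BB04) in regimens of 1–4 products, weights
  favouring dual therapy;
* per-refill pack duration drawn from the two market pack sizes
  {28, 84} days (60/40), refill-timing jitter uniform on ±3 days;
* a 25% per-refill probability of a 90–330 day non-persistence gap. This
  rate pairs with the 0.8 trim percentile: the estimator assumes roughly
  the top fifth of waiting times are gaps, and the generator realises
  that assumption, as a generator emulating two-thirds adherence in an
  elderly population plausibly should;
* staggered start offsets (0–120 days), one regimen with a
  discontinuation, index dates uniform over 1996–2016;
* decoy patients violating the washout (a pre-enrollment-window
  redemption less than 365 days before the index) and decoy redemptions
  after follow-up, to exercise the cohort filters.

Ground truth pours each dispensed pack's true duration from its
redemption day with carry-over, capped at follow-up, so truth is the
supplied-day set an omniscient observer would record.

The day-level oracle runs in two modes. **Episode mode** enumerates
co-exposed days from the *pipeline's own* treatment episodes — it
validates the interval algebra (Steps 2–3) in isolation, mirroring a
manual audit of the method's classification, and is the mode the
accuracy harness reports. **Truth mode** enumerates from generator ground
truth and validates the whole pipeline including duration estimation; it
is exact in the noiseless limit (no jitter, no gaps, homogeneous pack
sizes — verified in the tests) but not in general, because estimated
durations are statistical summaries, not oracles of individual packs.
Passing the episode-mode audit at 100% therefore demonstrates that the
interval algebra introduces no error beyond duration estimation; it does
not certify that estimated durations equal true supply on real data, and
no desk-scale simulation could.

The generator does not attempt demographic realism (no income, education
or mortality structure), seasonal prescribing, dose changes, or
stockpiling beyond the carry-over model.

## Problem sizes and numerical choices

The accuracy audit uses 650 simulated patients (yielding comfortably over
400 eligible co-exposed patients, the audit sample size) and the oracle
equivalence suite 1,400 patients; both complete in seconds to a couple of
minutes. Quantiles are type-7 throughout (trim bound and table quartiles).
k-means ties and silhouette ties resolve to the smallest k; singleton
clusters have silhouette 0. Degenerate inputs — empty registers, patients
with one redemption, censor day 0, empty waiting-time sets — all have
defined, tested behaviour rather than errors, except where the input
contradicts the design (records before the index date, unsorted event
sequences, registers too short for the washout), which raise immediately.

## Known limitations

* Durations come from refill behaviour; drugs with very few refills get
  the default fallback and wide uncertainty.
* The permissible gap and trim percentile are clinical judgment knobs;
  results should be reported with their values.
* Agent identity is the full-precision ATC code; substance-level
  collapsing (two codes, one substance) is a reporting concern left to
  the caller's coding of the register.
* The method reconstructs *coverage*, not ingestion; no register method
  can observe whether tablets were taken.
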