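test_that("the index event is the earliest exposure, gated by the age cap", {
  def <- cohort_definition()
  birth <- as.Date("2000-01-01")
  expect_equal(
    find_index_event(birth, as.Date(c("2006-01-01", "2005-03-01")), def),
    as.Date("2005-03-01"))
  # first exposure at age 19 disqualifies outright
  expect_true(is.na(find_index_event(birth, as.Date("2019-01-15"), def)))
  # the age cap is inclusive on fractional age (days/365.25): the last day
  # at or under exactly 18.0 years is admitted, the next day is not
  at_cap <- birth + floor(18 * 365.25)
  expect_false(is.na(find_index_event(birth, at_cap, def)))
  expect_true(is.na(find_index_event(birth, at_cap + 1, def)))
  expect_true(is.na(find_index_event(birth, character(0), def)))
})

test_that("persistence windows are closed intervals with day 0 at index", {
  def <- cohort_definition()
  idx <- as.Date("2010-01-01")
  expect_true(check_persistence(idx, idx + c(0, 150, 300, 400, 550, 700), def))
  # window [241,360] empty
  expect_false(check_persistence(idx, idx + c(0, 150, 400, 550, 700), def))
  # all exposures exactly on lower boundaries count (inclusive)
  expect_true(check_persistence(idx, idx + c(0, 121, 241, 361, 481, 601), def))
  # upper boundaries too
  expect_true(check_persistence(idx, idx + c(0, 240, 360, 480, 600, 730), def))
  # offsets one below the lower boundary fall into the previous window
  expect_false(check_persistence(idx, idx + c(0, 120, 241, 361, 481, 601), def))
})

test_that("cohort definition rejects malformed windows", {
  expect_error(cohort_definition(persistence_windows = list(c(100, 50))), "lo <= hi")
  expect_error(cohort_definition(persistence_windows = list(c(1, 200), c(150, 300))),
               "non-overlapping")
  expect_error(cohort_definition(persistence_windows = list(c(600, 800))),
               "within")
})

test_that("diagnosis and observation requirements exclude as specified", {
  sim <- generate_cdm(generator_config(n_patients = 20, seed = 3, p_dropout = 0))
  tabs <- sim$tables
  pid <- tabs$person$person_id[1]

  no_dx <- tabs
  no_dx$condition_occurrence <- no_dx$condition_occurrence[
    no_dx$condition_occurrence$person_id != pid, ]
  cohort <- build_cohort(no_dx)
  expect_false(pid %in% cohort$person_id)
  excl <- cohort_exclusions(no_dx)
  expect_equal(excl$reason[excl$person_id == pid], "no_epilepsy_diagnosis")
  # and a definition without the requirement admits the patient again
  cohort2 <- build_cohort(no_dx, cohort_definition(require_diagnosis = FALSE))
  expect_true(pid %in% cohort2$person_id)

  short_obs <- tabs
  i <- which(short_obs$observation_period$person_id == pid)
  idx <- min(tabs$drug_exposure$exposure_date[tabs$drug_exposure$person_id == pid])
  short_obs$observation_period$end_date[i] <- idx + 729
  # trim exposures beyond the shortened period to keep the bundle valid
  keep <- short_obs$drug_exposure$person_id != pid |
    short_obs$drug_exposure$exposure_date <= idx + 729
  short_obs$drug_exposure <- short_obs$drug_exposure[keep, ]
  expect_false(pid %in% build_cohort(short_obs)$person_id)
  excl <- cohort_exclusions(short_obs)
  expect_equal(excl$reason[excl$person_id == pid], "insufficient_observation")
})

test_that("build_cohort matches the brute-force oracle on random instances", {
  set.seed(42)
  for (k in 1:12) {
    sim <- random_instance(seed = 9000 + k)
    got <- build_cohort(sim$tables)
    want <- oracle_build_cohort(sim$tables)
    expect_equal(got$person_id, want$person_id)
    expect_equal(got$index_date, want$index_date)
    expect_equal(got$age_at_index, want$age_at_index, tolerance = 1e-12)
    expect_equal(got$followup_days, want$followup_days)
  }
})

test_that("removing a persistence window never shrinks the cohort", {
  sim <- generate_cdm(generator_config(n_patients = 150, seed = 55,
                                       p_dropout = 0.4))
  full <- cohort_definition()
  base <- build_cohort(sim$tables, full)$person_id
  for (drop in seq_along(full$persistence_windows)) {
    sub <- cohort_definition(
      persistence_windows = full$persistence_windows[-drop])
    wider <- build_cohort(sim$tables, sub)$person_id
    expect_true(all(base %in% wider))
  }
  # adding a window never grows it
  stricter <- cohort_definition(persistence_windows = c(
    list(c(1L, 120L)), full$persistence_windows))
  expect_true(all(build_cohort(sim$tables, stricter)$person_id %in% base))
})

test_that("cohort output is independent of input row order", {
  sim <- generate_cdm(generator_config(n_patients = 80, seed = 77,
                                       p_dropout = 0.3))
  tabs <- sim$tables
  set.seed(1)
  shuf <- tabs
  for (nm in c("person", "observation_period", "drug_exposure",
               "condition_occurrence")) {
    shuf[[nm]] <- shuf[[nm]][sample(nrow(shuf[[nm]])), ]
  }
  expect_equal(build_cohort(shuf), build_cohort(tabs))
})
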