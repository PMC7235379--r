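# minimal valid bundle with free-form conditions for classification tests
mk_bundle <- function(cond_ids, cond_days = rep(0, length(cond_ids))) {
  idx <- as.Date("2010-06-01")
  person <- tibble::tibble(person_id = 1L, sex = "male",
                           birth_date = as.Date("2002-01-01"))
  obs <- tibble::tibble(person_id = 1L, start_date = idx - 30,
                        end_date = idx + 800)
  expo <- tibble::tibble(person_id = 1L, drug_concept_id = 7001L,
                         exposure_date = idx + c(0, 150, 300, 420, 550, 650))
  cond <- tibble::tibble(person_id = rep(1L, length(cond_ids)),
                         condition_concept_id = as.integer(cond_ids),
                         condition_start_date = idx + cond_days)
  cdm_tables(person, obs, expo, cond)
}

test_that("epilepsy category comes from the classifying diagnosis", {
  tabs <- mk_bundle(4185733)            # BECTS is a focal syndrome
  cohort <- build_cohort(tabs)
  expect_equal(classify_epilepsy_type(tabs, cohort)$epilepsy_type, "focal")

  tabs <- mk_bundle(4179936)            # CAE is generalized
  expect_equal(classify_epilepsy_type(tabs, build_cohort(tabs))$epilepsy_type,
               "generalized")

  tabs <- mk_bundle(123456)             # unknown concept
  expect_equal(classify_epilepsy_type(tabs, build_cohort(tabs))$epilepsy_type,
               "unclassified")
})

test_that("multi-diagnosis patients classify by frequency, then date, then id", {
  # CAE then LGS, LGS more frequent -> LGS wins
  tabs <- mk_bundle(c(4179936, 4046213, 4046213), cond_days = c(0, 5, 10))
  cohort <- build_cohort(tabs)
  expect_equal(syndrome_stratum(tabs, cohort)$syndrome, "LGS")
  # equal frequency -> earliest date wins
  tabs <- mk_bundle(c(4046213, 4179936), cond_days = c(3, 0))
  expect_equal(syndrome_stratum(tabs, build_cohort(tabs))$syndrome, "CAE")
  # same frequency and date -> lowest concept id (374915 focal NOS)
  tabs <- mk_bundle(c(4055361, 374915), cond_days = c(0, 0))
  expect_equal(classify_epilepsy_type(tabs, build_cohort(tabs))$epilepsy_type,
               "focal")
})

test_that("syndrome stratum requires a tagged concept", {
  tabs <- mk_bundle(4046213)            # LGS
  expect_equal(syndrome_stratum(tabs, build_cohort(tabs))$syndrome, "LGS")
  tabs <- mk_bundle(374915)             # focal NOS has no syndrome tag
  expect_equal(syndrome_stratum(tabs, build_cohort(tabs))$syndrome, "none")
})

test_that("onset-age strata implement the half-closed partition", {
  expect_equal(onset_age_stratum(c(3.9, 4.0, 13.0, 13.5, 0, 18)),
               c("<4", "4-13", "4-13", ">13", "<4", ">13"))
  expect_error(onset_age_stratum(19), "outside")
  expect_error(onset_age_stratum(-1), "outside")
})

test_that("each stratification kind partitions the cohort", {
  sim <- generate_cdm(make_paperlike_config(300, seed = 41, p_dropout = 0.2))
  cohort <- build_cohort(sim$tables)
  for (kind in c("epilepsy_type", "onset_age", "syndrome", "all")) {
    st <- stratify_cohort(sim$tables, cohort, kind)
    expect_setequal(st$person_id, cohort$person_id)
    expect_false(any(duplicated(st$person_id)))
    expect_false(any(is.na(st$stratum)))
  }
})

test_that("stratified pathway summaries cover exactly the stratum members", {
  sim <- generate_cdm(make_paperlike_config(400, seed = 43, p_dropout = 0))
  cohort <- build_cohort(sim$tables)
  seqs <- build_sequences(sim$tables, cohort)
  st <- stratified_pathways(sim$tables, cohort, seqs, "epilepsy_type")
  expect_named(st, c("focal", "generalized", "unclassified"))
  expect_equal(sum(vapply(st, function(s) s$n_members, 0)), nrow(cohort))
  for (s in st) {
    expect_equal(sum(s$distribution$n), s$n_members)
    expect_equal(attr(s$pathways, "total_patients"), s$n_members)
  }
  # all-monotherapy stratum has DRE% = 0
  mono <- seqs
  mono$n_distinct <- 1L
  mono$is_dre <- FALSE
  mono$ingredients <- lapply(seq_len(nrow(mono)), function(i) "valproic acid")
  mono$sequence <- "valproic acid"
  st_all <- stratified_pathways(sim$tables, cohort, mono, "all")
  expect_equal(st_all$all$dre_pct, 0)
  # empty strata are present with zero counts
  no_lgs <- sim$tables
  keep <- !no_lgs$condition_occurrence$condition_concept_id %in% 4046213L
  no_lgs$condition_occurrence$condition_concept_id[!keep] <- 4055361L
  st_syn <- stratified_pathways(no_lgs, cohort, seqs, "syndrome")
  expect_equal(st_syn$LGS$n_members, 0)
  expect_true(is.na(st_syn$LGS$dre_pct))
})

test_that("per-stratum DRE rates recover generator ground truth", {
  sim <- generate_cdm(make_paperlike_config(2000, seed = 47, p_dropout = 0))
  cohort <- build_cohort(sim$tables)
  seqs <- build_sequences(sim$tables, cohort)
  st <- stratified_pathways(sim$tables, cohort, seqs, "syndrome")
  truth <- sim$ground_truth
  v <- default_vocabulary()
  tag <- v$syndrome_tag[match(truth$true_syndrome, v$concept_id)]
  for (s in c("LGS", "CAE", "BECTS")) {
    ids <- truth$person_id[!is.na(tag) & tag == s]
    true_rate <- mean(vapply(truth$true_sequence[truth$person_id %in% ids],
                             length, 0L) >= 3)
    m <- length(ids)
    se <- sqrt(true_rate * (1 - true_rate) / m)
    expect_lt(abs(st[[s]]$dre_pct / 100 - true_rate), 3 * se + 1e-9)
  }
})

test_that("annual monotherapy trend counts exclusive-ingredient person-years", {
  idx <- as.Date("2010-03-01")
  person <- tibble::tibble(person_id = 1:2, sex = c("male", "female"),
                           birth_date = as.Date("2002-01-01"))
  obs <- tibble::tibble(person_id = 1:2, start_date = idx - 10,
                        end_date = idx + 1200)
  expo <- dplyr::bind_rows(
    # person 1: VPA only in 2010 -> counts; VPA + OXC in 2011 -> excluded
    tibble::tibble(person_id = 1L, drug_concept_id = 7001L,
                   exposure_date = idx + c(0, 130, 250, 400, 500, 640)),
    tibble::tibble(person_id = 1L, drug_concept_id = 7002L,
                   exposure_date = idx + c(400, 640)),
    # person 2: VPA monotherapy throughout
    tibble::tibble(person_id = 2L, drug_concept_id = 7001L,
                   exposure_date = idx + c(1, 131, 251, 401, 501, 641)))
  cond <- tibble::tibble(person_id = 1:2, condition_concept_id = 374915L,
                         condition_start_date = idx)
  tabs <- cdm_tables(person, obs, expo, cond)
  cohort <- build_cohort(tabs)
  expect_equal(nrow(cohort), 2)
  tr <- annual_monotherapy_trend(tabs, cohort)
  get <- function(y, d) {
    hit <- tr$n_patients[tr$year == y & tr$ingredient == d]
    if (length(hit) == 0) 0L else hit
  }
  expect_equal(get(2010, "valproic acid"), 2L)
  expect_equal(get(2011, "valproic acid"), 1L)   # person 2 only
  expect_equal(get(2011, "oxcarbazepine"), 0L)   # person 1 on two drugs
})

test_that("yearly monotherapy counts never exceed exposed members", {
  sim <- generate_cdm(make_paperlike_config(300, seed = 53, p_dropout = 0.1))
  cohort <- build_cohort(sim$tables)
  tr <- annual_monotherapy_trend(sim$tables, cohort)
  dx <- sim$tables$drug_exposure[
    sim$tables$drug_exposure$person_id %in% cohort$person_id, ]
  dx$year <- as.integer(format(dx$exposure_date, "%Y"))
  for (y in unique(tr$year)) {
    exposed <- length(unique(dx$person_id[dx$year == y]))
    expect_lte(sum(tr$n_patients[tr$year == y]), exposed)
  }
})

test_that("injected first-line preference drift shows up in the trend table", {
  drift <- tibble::tibble(year = rep(2005:2012, each = 1),
                          ingredient = "valproic acid",
                          weight = seq(4, 0.1, length.out = 8))
  cfg <- generator_config(n_patients = 500, seed = 59, p_dropout = 0,
                          calendar_span = as.Date(c("2005-01-01", "2014-12-31")),
                          calendar_trend = drift)
  sim <- generate_cdm(cfg)
  cohort <- build_cohort(sim$tables)
  tr <- annual_monotherapy_trend(sim$tables, cohort)
  share <- function(years) {
    sub <- tr[tr$year %in% years, ]
    sum(sub$n_patients[sub$ingredient == "valproic acid"]) / sum(sub$n_patients)
  }
  expect_gt(share(2005:2007), share(2010:2012))
})
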