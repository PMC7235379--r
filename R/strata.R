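# winning epilepsy diagnosis per person: most frequent concept, ties broken
# by earliest condition_start_date, then lowest concept_id
winning_condition <- function(conditions) {
  if (nrow(conditions) == 0) {
    return(tibble::tibble(person_id = integer(), condition_concept_id = integer()))
  }
  conditions |>
    dplyr::group_by(.data$person_id, .data$condition_concept_id) |>
    dplyr::summarise(n = dplyr::n(),
                     first_date = min(.data$condition_start_date),
                     .groups = "drop") |>
    dplyr::group_by(.data$person_id) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$first_date,
                   .data$condition_concept_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("person_id", "condition_concept_id")
}

#' Classify each cohort member's epilepsy category
#'
#' Assigns focal / generalized / unclassified from the member's epilepsy
#' diagnoses. When a member carries several distinct epilepsy concepts the
#' most frequent one classifies them, with ties broken by earliest
#' condition start date and then lowest concept id (an explicit,
#' configurable-by-replacement policy — source records do not say how
#' multi-diagnosis patients should be assigned). Concepts absent from the
#' vocabulary classify as unclassified.
#'
#' @param tables A `cdm_tables` object.
#' @param cohort Cohort tibble from [build_cohort()].
#' @return Tibble `person_id`, `epilepsy_type` ("focal", "generalized",
#'   "unclassified").
#' @export
classify_epilepsy_type <- function(tables, cohort) {
  win <- winning_condition(
    tables$condition_occurrence[
      tables$condition_occurrence$person_id %in% cohort$person_id, ])
  vocab <- tables$concept
  grp <- vocab$condition_group[match(win$condition_concept_id, vocab$concept_id)]
  win$epilepsy_type <- ifelse(is.na(grp), "unclassified", grp)
  out <- dplyr::left_join(cohort["person_id"],
                          win[c("person_id", "epilepsy_type")],
                          by = "person_id")
  out$epilepsy_type[is.na(out$epilepsy_type)] <- "unclassified"
  out
}

#' Onset-age stratum
#'
#' Bins age at index into the three onset groups: under 4 years, 4 to 13
#' years, over 13 years — implemented as the half-closed partition
#' `[0, 4)`, `[4, 13]`, `(13, 18]`.
#'
#' @param age_at_index Numeric vector of ages in years, within `[0, 18]`
#'   (a small tolerance above 18 is allowed for day-rounding).
#' @return Character vector in `c("<4", "4-13", ">13")`.
#' @export
onset_age_stratum <- function(age_at_index) {
  if (any(age_at_index < 0 | age_at_index > 18.05, na.rm = TRUE)) {
    stop("age_at_index outside [0, 18]", call. = FALSE)
  }
  dplyr::case_when(age_at_index < 4 ~ "<4",
                   age_at_index <= 13 ~ "4-13",
                   TRUE ~ ">13")
}

#' Syndrome stratum
#'
#' Returns the electro-clinical syndrome (LGS, CAE or BECTS) of each
#' member's classifying diagnosis (same winning-concept policy as
#' [classify_epilepsy_type()]), or `"none"` when the classifying concept
#' carries no syndrome tag.
#'
#' @inheritParams classify_epilepsy_type
#' @return Tibble `person_id`, `syndrome` ("LGS", "CAE", "BECTS", "none").
#' @export
syndrome_stratum <- function(tables, cohort) {
  win <- winning_condition(
    tables$condition_occurrence[
      tables$condition_occurrence$person_id %in% cohort$person_id, ])
  vocab <- tables$concept
  tag <- vocab$syndrome_tag[match(win$condition_concept_id, vocab$concept_id)]
  win$syndrome <- ifelse(!is.na(tag) & tag %in% c("LGS", "CAE", "BECTS"),
                         tag, "none")
  out <- dplyr::left_join(cohort["person_id"],
                          win[c("person_id", "syndrome")], by = "person_id")
  out$syndrome[is.na(out$syndrome)] <- "none"
  out
}

stratum_levels <- list(
  epilepsy_type = c("focal", "generalized", "unclassified"),
  onset_age = c("<4", "4-13", ">13"),
  syndrome = c("LGS", "CAE", "BECTS", "none"),
  all = "all")

#' Assign each cohort member to a stratum
#'
#' For one stratification kind, returns the member-to-stratum assignment.
#' Within a kind the strata are disjoint and — including the remainder
#' stratum ("unclassified" / "none") — cover the cohort.
#'
#' @inheritParams classify_epilepsy_type
#' @param kind One of "epilepsy_type", "onset_age", "syndrome", "all".
#' @return Tibble `person_id`, `stratum`.
#' @export
stratify_cohort <- function(tables, cohort,
                            kind = c("epilepsy_type", "onset_age",
                                     "syndrome", "all")) {
  kind <- match.arg(kind)
  stratum <- switch(kind,
    epilepsy_type = classify_epilepsy_type(tables, cohort)$epilepsy_type,
    onset_age = onset_age_stratum(cohort$age_at_index),
    syndrome = syndrome_stratum(tables, cohort)$syndrome,
    all = rep("all", nrow(cohort)))
  tibble::tibble(person_id = cohort$person_id, stratum = stratum)
}

#' Per-stratum pathway analyses
#'
#' Re-runs the pathway summaries ([count_pathways()],
#' [asm_count_distribution()], DRE fraction) on each stratum's members.
#' Every stratum level of the kind is present in the result, including
#' empty ones (zero counts, `NA` DRE percentage).
#'
#' @inheritParams classify_epilepsy_type
#' @param sequences Tibble from [build_sequences()] covering the cohort.
#' @param kind Stratification kind, see [stratify_cohort()].
#' @return Named list (one element per stratum) of lists with `n_members`,
#'   `pathways` (a `pathway_table`), `distribution` and `dre_pct`.
#' @export
stratified_pathways <- function(tables, cohort, sequences,
                                kind = c("epilepsy_type", "onset_age",
                                         "syndrome", "all")) {
  kind <- match.arg(kind)
  assign_tbl <- stratify_cohort(tables, cohort, kind)
  lvls <- stratum_levels[[kind]]
  out <- lapply(lvls, function(lv) {
    ids <- assign_tbl$person_id[assign_tbl$stratum == lv]
    seqs <- sequences[sequences$person_id %in% ids, ]
    list(n_members = nrow(seqs),
         pathways = count_pathways(seqs),
         distribution = asm_count_distribution(seqs),
         dre_pct = if (nrow(seqs) == 0) NA_real_
                   else round(100 * mean(seqs$is_dre), 1))
  })
  names(out) <- lvls
  out
}

#' Annual monotherapy prescription trend
#'
#' For each calendar year and ASM ingredient, counts the cohort members who
#' were on monotherapy with that ingredient during the year: at least one
#' exposure to it and none to any other ASM ingredient in that year. A
#' member exposed to two or more ingredients in a year contributes to no
#' ingredient for that year.
#'
#' @inheritParams classify_epilepsy_type
#' @return Tibble `year`, `ingredient` (name), `n_patients`, sorted by year
#'   then ingredient.
#' @export
annual_monotherapy_trend <- function(tables, cohort) {
  vocab <- tables$concept
  drug_ids <- vocab$concept_id[!is.na(vocab$drug_class) &
                                 vocab$drug_class == "N03A_ingredient"]
  dx <- tables$drug_exposure[
    tables$drug_exposure$drug_concept_id %in% drug_ids &
      tables$drug_exposure$person_id %in% cohort$person_id, ]
  if (nrow(dx) == 0) {
    return(tibble::tibble(year = integer(), ingredient = character(),
                          n_patients = integer()))
  }
  dx$year <- as.integer(format(dx$exposure_date, "%Y"))
  dx |>
    dplyr::distinct(.data$person_id, .data$year, .data$drug_concept_id) |>
    dplyr::group_by(.data$person_id, .data$year) |>
    dplyr::filter(dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::count(.data$year, .data$drug_concept_id, name = "n_patients") |>
    dplyr::mutate(ingredient = ingredient_names(.data$drug_concept_id, vocab)) |>
    dplyr::select("year", "ingredient", "n_patients") |>
    dplyr::arrange(.data$year, .data$ingredient)
}
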