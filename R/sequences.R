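#' Classify drug resistance from the distinct-ASM count
#'
#' Drug-resistant epilepsy (DRE) is operationalized as the add-on of a third
#' distinct ASM ingredient within the sequencing window: a sequence is
#' drug-resistant iff it contains at least `threshold` (default 3) distinct
#' ingredients.
#'
#' @param n_distinct Integer vector of distinct-ingredient counts.
#' @param threshold DRE threshold (default 3).
#' @return Logical vector.
#' @export
classify_dre <- function(n_distinct, threshold = 3L) {
  n_distinct >= threshold
}

#' Build one patient's ordered treatment sequence
#'
#' The treatment sequence is the list of distinct ASM ingredients in order
#' of first exposure, restricted to exposures within `window_days` of the
#' index (day 0, both ends inclusive) and truncated to the first `cap`
#' ingredients. Switching and adding are deliberately not distinguished:
#' a new ingredient extends the sequence regardless of whether earlier
#' drugs continue. Same-day first exposures are ordered by concept id.
#'
#' @param index_date The member's index date.
#' @param exposures Tibble of the member's ASM exposures with columns
#'   `drug_concept_id`, `exposure_date`.
#' @param window_days Sequencing window in days after index (default 730,
#'   the initial two treatment years); `NULL` means full follow-up.
#' @param cap Maximum sequence length (default 20).
#' @param dre_threshold Distinct-ASM count defining drug resistance.
#' @return A list with `ingredients` (integer concept ids, first-appearance
#'   order), `n_distinct` and `is_dre`.
#' @export
build_sequence <- function(index_date, exposures, window_days = 730L,
                           cap = 20L, dre_threshold = 3L) {
  offs <- as.integer(exposures$exposure_date - index_date)
  keep <- offs >= 0 & (if (is.null(window_days)) TRUE else offs <= window_days)
  if (!any(keep)) {
    stop("cohort member has no in-window exposures; ",
         "inconsistent with cohort construction", call. = FALSE)
  }
  ex <- exposures[keep, ]
  ex <- ex[order(ex$exposure_date, ex$drug_concept_id), ]
  ing <- ex$drug_concept_id[!duplicated(ex$drug_concept_id)]
  ing <- head(ing, cap)
  list(ingredients = as.integer(ing), n_distinct = length(ing),
       is_dre = classify_dre(length(ing), dre_threshold))
}

#' Build treatment sequences for a whole cohort
#'
#' Applies [build_sequence()] to every cohort member's N03A ingredient
#' exposures and renders each sequence as ingredient names joined by
#' "\\u2192" arrows.
#'
#' @param tables A `cdm_tables` object.
#' @param cohort Cohort tibble from [build_cohort()].
#' @param window_days,cap,dre_threshold Passed to [build_sequence()].
#' @return Tibble with columns `person_id`, `ingredients` (list-column of
#'   ingredient names), `sequence` (display string), `n_distinct`, `is_dre`,
#'   sorted by `person_id`.
#' @export
build_sequences <- function(tables, cohort, window_days = 730L, cap = 20L,
                            dre_threshold = 3L) {
  vocab <- tables$concept
  drug_ids <- vocab$concept_id[!is.na(vocab$drug_class) &
                                 vocab$drug_class == "N03A_ingredient"]
  dx <- tables$drug_exposure[tables$drug_exposure$drug_concept_id %in% drug_ids, ]
  ex_split <- split(dx[c("drug_concept_id", "exposure_date")], dx$person_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$person_id[i]
    s <- build_sequence(cohort$index_date[i], ex_split[[as.character(pid)]],
                        window_days = window_days, cap = cap,
                        dre_threshold = dre_threshold)
    nms <- ingredient_names(s$ingredients, vocab)
    tibble::tibble(person_id = pid, ingredients = list(nms),
                   sequence = paste(nms, collapse = "\u2192"),
                   n_distinct = s$n_distinct, is_dre = s$is_dre)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(cohort) == 0) {
    out <- tibble::tibble(person_id = integer(), ingredients = list(),
                          sequence = character(), n_distinct = integer(),
                          is_dre = logical())
  }
  dplyr::arrange(out, .data$person_id)
}

#' Count distinct treatment pathways
#'
#' Exact frequency table of the distinct ordered sequences, ordered by
#' descending patient count and then lexicographically by the sequence
#' string (deterministic for fixed input).
#'
#' @param sequences Tibble from [build_sequences()].
#' @return A `pathway_table`: tibble with columns `sequence`, `ingredients`
#'   (list-column) and `n_patients`, with attribute `total_patients`.
#' @export
count_pathways <- function(sequences) {
  if (nrow(sequences) == 0) {
    out <- tibble::tibble(sequence = character(), ingredients = list(),
                          n_patients = integer())
  } else {
    out <- sequences |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(ingredients = .data$ingredients[1],
                       n_patients = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n_patients), .data$sequence)
  }
  attr(out, "total_patients") <- nrow(sequences)
  class(out) <- c("pathway_table", class(out))
  out
}

#' Distribution of the number of ASMs used
#'
#' Partitions the cohort by distinct-ASM count into the classes `1`, `2`
#' and `3+` (the `3+` class is the drug-resistant fraction under the
#' default threshold) with percentages rounded to one decimal.
#'
#' @param sequences Tibble from [build_sequences()].
#' @return Tibble with columns `n_asm` ("1", "2", "3+"), `n` and `pct`.
#' @export
asm_count_distribution <- function(sequences) {
  n_asm <- cut(sequences$n_distinct, breaks = c(0, 1, 2, Inf),
               labels = c("1", "2", "3+"))
  counts <- table(factor(n_asm, levels = c("1", "2", "3+")))
  total <- nrow(sequences)
  tibble::tibble(
    n_asm = names(counts), n = as.integer(counts),
    pct = if (total == 0) rep(NA_real_, 3)
          else round(100 * as.integer(counts) / total, 1))
}

#' Ingredient usage shares
#'
#' `mode = "slot"` (default): each position of each patient's sequence is
#' one slot; an ingredient's share is its slot count over the total number
#' of slots (shares sum to 1). `mode = "patient"`: share of patients whose
#' pathway contains the ingredient (shares need not sum to 1).
#'
#' @param sequences Tibble from [build_sequences()].
#' @param mode "slot" or "patient".
#' @return Tibble with columns `ingredient`, `n`, `share`, sorted by
#'   descending share then ingredient.
#' @export
asm_frequency <- function(sequences, mode = c("slot", "patient")) {
  mode <- match.arg(mode)
  slots <- unlist(lapply(sequences$ingredients, unique))
  if (length(slots) == 0) {
    return(tibble::tibble(ingredient = character(), n = integer(),
                          share = numeric()))
  }
  counts <- table(slots)
  denom <- if (mode == "slot") sum(counts) else nrow(sequences)
  tibble::tibble(ingredient = names(counts), n = as.integer(counts),
                 share = as.integer(counts) / denom) |>
    dplyr::arrange(dplyr::desc(.data$share), .data$ingredient)
}
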