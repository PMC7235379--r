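#' Bundled epilepsy condition concepts
#'
#' The 20-concept epilepsy condition set used throughout the package: 10
#' focal, 9 generalized and 1 unclassified concept, each with its category
#' (`condition_group`), an electro-clinical syndrome tag where one applies
#' (LGS, CAE, BECTS), and the reference pediatric-cohort patient count that
#' weights the default syndrome mixture of [make_paperlike_config()].
#' The unclassified concept id (9999999) is synthetic: unclassified patients
#' in the reference cohort carry no single source concept.
#'
#' @return A tibble with columns `concept_id`, `concept_name`,
#'   `condition_group` (focal/generalized/unclassified), `syndrome_tag`
#'   (LGS/CAE/BECTS/other) and `ref_n` (reference cohort count).
#' @export
epilepsy_concepts <- function() {
  tibble::tribble(
    ~concept_id, ~concept_name, ~condition_group, ~syndrome_tag, ~ref_n,
    374915L,  "Localization-related epilepsy, not otherwise specified", "focal", "other", 613L,
    4185733L, "Benign epilepsy with centrotemporal spikes",             "focal", "BECTS",  67L,
    4102345L, "Temporal lobe epilepsy",                                 "focal", "other",  49L,
    4044080L, "Childhood occipital epilepsy (Panayiotopoulos type)",    "focal", "other",  44L,
    4047888L, "Frontal lobe epilepsy",                                  "focal", "other",  26L,
    4046207L, "Occipital lobe epilepsy (Gastaut type)",                 "focal", "other",  24L,
    4043551L, "Epilepsy with continuous spike wave during slow-wave sleep", "focal", "other", 4L,
    4044084L, "Supplementary motor area epilepsy",                      "focal", "other",   4L,
    4046206L, "Parietal lobe epilepsy",                                 "focal", "other",   3L,
    4041672L, "Rasmussen syndrome",                                     "focal", "other",   1L,
    4055361L, "Generalized epilepsy, not otherwise specified",          "generalized", "other", 137L,
    4179936L, "Childhood absence epilepsy",                             "generalized", "CAE",   56L,
    376105L,  "West syndrome",                                          "generalized", "other", 44L,
    4046213L, "Lennox-Gastaut syndrome",                                "generalized", "LGS",   38L,
    4267274L, "Juvenile myoclonic epilepsy",                            "generalized", "other", 34L,
    4046210L, "Juvenile absence epilepsy",                              "generalized", "other", 15L,
    4047897L, "Epilepsy with grand mal seizures on awakening",          "generalized", "other", 10L,
    4043413L, "Myoclonic astatic epilepsy",                             "generalized", "other",  5L,
    4044225L, "Myoclonic absence epilepsy",                             "generalized", "other",  5L,
    9999999L, "Epilepsy, unclassified (synthetic)",                     "unclassified", "other", 12L
  )
}

#' Bundled ASM ingredient concepts
#'
#' Ingredient-level anti-seizure-medication (ATC class N03A) concepts used by
#' the synthetic generator and the bundled vocabulary. Concept ids are
#' synthetic (7001+); names are the real ingredient names.
#'
#' @return A tibble with columns `concept_id`, `concept_name`.
#' @export
asm_ingredients <- function() {
  tibble::tribble(
    ~concept_id, ~concept_name,
    7001L, "valproic acid",
    7002L, "oxcarbazepine",
    7003L, "lamotrigine",
    7004L, "levetiracetam",
    7005L, "topiramate",
    7006L, "phenobarbital",
    7007L, "rufinamide",
    7008L, "perampanel",
    7009L, "carbamazepine",
    7010L, "clobazam",
    7011L, "ethosuximide",
    7012L, "vigabatrin",
    7013L, "zonisamide",
    7014L, "lacosamide"
  )
}

#' Reference cohort demographics
#'
#' Headline demographic constants of the reference pediatric epilepsy cohort
#' that the paper-like generator preset emulates: total cohort size and the
#' male/female split used for the sex mixture.
#'
#' @return Named list with `n_total`, `n_male`, `n_female`.
#' @export
reference_demographics <- function() {
  list(n_total = 1192L, n_male = 653L, n_female = 539L)
}

#' Build the default vocabulary table
#'
#' Combines the bundled epilepsy condition concepts and ASM ingredient
#' concepts into a single `concept` table. Drug concepts are flagged
#' `N03A_ingredient`; condition concepts carry their `condition_group` and
#' `syndrome_tag`.
#'
#' @return A tibble with columns `concept_id`, `concept_name`, `domain`,
#'   `drug_class`, `condition_group`, `syndrome_tag`.
#' @export
#' @examples
#' v <- default_vocabulary()
#' table(v$domain)
default_vocabulary <- function() {
  conds <- epilepsy_concepts()
  drugs <- asm_ingredients()
  dplyr::bind_rows(
    tibble::tibble(
      concept_id = drugs$concept_id,
      concept_name = drugs$concept_name,
      domain = "drug",
      drug_class = "N03A_ingredient",
      condition_group = NA_character_,
      syndrome_tag = NA_character_
    ),
    tibble::tibble(
      concept_id = conds$concept_id,
      concept_name = conds$concept_name,
      domain = "condition",
      drug_class = NA_character_,
      condition_group = conds$condition_group,
      syndrome_tag = conds$syndrome_tag
    )
  )
}

#' Resolve a drug concept to its ingredient-level concept
#'
#' Treatment sequences are mined at the RxNorm-ingredient level. The bundled
#' vocabulary is already ingredient-level, so resolution is the identity for
#' its drug concepts; vocabularies extended with an `ingredient_concept_id`
#' column (mapping e.g. branded products to ingredients) resolve through
#' that column.
#'
#' @param drug_concept_id Integer vector of drug concept ids.
#' @param vocabulary A vocabulary tibble as from [default_vocabulary()],
#'   optionally with an `ingredient_concept_id` column.
#' @return Integer vector of ingredient concept ids.
#' @export
resolve_ingredient <- function(drug_concept_id, vocabulary = default_vocabulary()) {
  idx <- match(drug_concept_id, vocabulary$concept_id)
  if (anyNA(idx)) {
    bad <- unique(drug_concept_id[is.na(idx)])
    stop("unknown drug concept id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if ("ingredient_concept_id" %in% names(vocabulary)) {
    mapped <- vocabulary$ingredient_concept_id[idx]
    out <- ifelse(is.na(mapped), drug_concept_id, mapped)
    as.integer(out)
  } else {
    as.integer(drug_concept_id)
  }
}

# names for a vector of ingredient concept ids (internal)
ingredient_names <- function(concept_ids, vocabulary) {
  vocabulary$concept_name[match(concept_ids, vocabulary$concept_id)]
}
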