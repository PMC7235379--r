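#' Assemble a minimal OMOP-CDM table bundle
#'
#' Bundles the five relational tables the pipeline consumes — person,
#' observation_period, drug_exposure, condition_occurrence and the concept
#' vocabulary — into a single validated object.
#'
#' @param person Tibble: `person_id` (unique positive integer), `sex`
#'   ("male"/"female"), `birth_date` (Date).
#' @param observation_period Tibble: `person_id`, `start_date`, `end_date`.
#'   At most one period per person.
#' @param drug_exposure Tibble: `person_id`, `drug_concept_id`,
#'   `exposure_date`. One row per prescription event (point events, not eras).
#' @param condition_occurrence Tibble: `person_id`, `condition_concept_id`,
#'   `condition_start_date`.
#' @param concept Vocabulary tibble, defaults to [default_vocabulary()].
#' @param validate Run [validate_cdm()] on the result (default TRUE).
#' @return An object of class `cdm_tables` (a named list of the five tibbles).
#' @export
cdm_tables <- function(person, observation_period, drug_exposure,
                       condition_occurrence, concept = default_vocabulary(),
                       validate = TRUE) {
  tables <- structure(
    list(
      person = tibble::as_tibble(person),
      observation_period = tibble::as_tibble(observation_period),
      drug_exposure = tibble::as_tibble(drug_exposure),
      condition_occurrence = tibble::as_tibble(condition_occurrence),
      concept = tibble::as_tibble(concept)
    ),
    class = "cdm_tables"
  )
  if (validate) validate_cdm(tables)
  tables
}

#' @export
print.cdm_tables <- function(x, ...) {
  cat("<cdm_tables>\n")
  for (nm in names(x)) cat(sprintf("  %-21s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

empty_person <- function() {
  tibble::tibble(person_id = integer(), sex = character(),
                 birth_date = as.Date(character()))
}
empty_observation_period <- function() {
  tibble::tibble(person_id = integer(), start_date = as.Date(character()),
                 end_date = as.Date(character()))
}
empty_drug_exposure <- function() {
  tibble::tibble(person_id = integer(), drug_concept_id = integer(),
                 exposure_date = as.Date(character()))
}
empty_condition_occurrence <- function() {
  tibble::tibble(person_id = integer(), condition_concept_id = integer(),
                 condition_start_date = as.Date(character()))
}

#' An empty, valid CDM bundle
#'
#' @param concept Vocabulary tibble (default bundled vocabulary).
#' @return A `cdm_tables` object with zero persons.
#' @export
empty_cdm_tables <- function(concept = default_vocabulary()) {
  cdm_tables(empty_person(), empty_observation_period(), empty_drug_exposure(),
             empty_condition_occurrence(), concept)
}

#' List referential-integrity and schema problems of a CDM bundle
#'
#' Total validation pass: every problem row is reported, not just the first.
#' Checked: required columns; unique person and concept ids; sex values;
#' at most one observation period per person with start <= end; all foreign
#' keys resolve to a person; drug concepts resolvable in the vocabulary as
#' ingredients; exposure dates inside the person's observation period; birth
#' date preceding all of the person's event dates; no missing dates.
#' Condition concepts absent from the vocabulary are NOT problems — they
#' classify as "unclassified" downstream.
#'
#' @param tables A `cdm_tables` object (or plain list of the five tibbles).
#' @return Tibble with columns `table`, `row` (row number, NA for
#'   table-level problems) and `problem`.
#' @export
cdm_problems <- function(tables) {
  probs <- list()
  add <- function(table, row, problem) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(
      table = table, row = as.integer(row), problem = problem)
  }

  required <- list(
    person = c("person_id", "sex", "birth_date"),
    observation_period = c("person_id", "start_date", "end_date"),
    drug_exposure = c("person_id", "drug_concept_id", "exposure_date"),
    condition_occurrence = c("person_id", "condition_concept_id",
                             "condition_start_date"),
    concept = c("concept_id", "concept_name", "domain")
  )
  for (nm in names(required)) {
    missing_cols <- setdiff(required[[nm]], names(tables[[nm]]))
    if (length(missing_cols) > 0) {
      add(nm, NA, paste0("missing column(s): ",
                         paste(missing_cols, collapse = ", ")))
    }
  }
  if (length(probs) > 0) return(dplyr::bind_rows(probs))

  p <- tables$person; op <- tables$observation_period
  dx <- tables$drug_exposure; co <- tables$condition_occurrence
  vc <- tables$concept

  dup <- which(duplicated(p$person_id))
  for (i in dup) add("person", i, paste0("duplicate person_id ", p$person_id[i]))
  bad_sex <- which(!p$sex %in% c("male", "female"))
  for (i in bad_sex) add("person", i, paste0("invalid sex '", p$sex[i], "'"))
  for (i in which(is.na(p$birth_date))) add("person", i, "missing birth_date")

  dupc <- which(duplicated(vc$concept_id))
  for (i in dupc) add("concept", i, paste0("duplicate concept_id ", vc$concept_id[i]))

  dup_op <- which(duplicated(op$person_id))
  for (i in dup_op) {
    add("observation_period", i,
        paste0("multiple observation periods for person_id ", op$person_id[i],
               " (at most one per person is supported)"))
  }
  for (i in which(is.na(op$start_date) | is.na(op$end_date))) {
    add("observation_period", i, "missing date")
  }
  inv <- which(!is.na(op$start_date) & !is.na(op$end_date) &
                 op$start_date > op$end_date)
  for (i in inv) add("observation_period", i, "start_date after end_date")

  fk <- function(nm, ids) {
    for (i in which(!ids %in% p$person_id)) {
      add(nm, i, paste0("person_id ", ids[i], " not in person table"))
    }
  }
  fk("observation_period", op$person_id)
  fk("drug_exposure", dx$person_id)
  fk("condition_occurrence", co$person_id)

  drug_ids <- vc$concept_id[!is.na(vc$domain) & vc$domain == "drug"]
  for (i in which(!dx$drug_concept_id %in% drug_ids)) {
    add("drug_exposure", i,
        paste0("drug_concept_id ", dx$drug_concept_id[i],
               " not resolvable to an ingredient in the vocabulary"))
  }
  for (i in which(is.na(dx$exposure_date))) add("drug_exposure", i, "missing exposure_date")
  for (i in which(is.na(co$condition_start_date))) {
    add("condition_occurrence", i, "missing condition_start_date")
  }

  # exposure inside the person's observation period; birth precedes events
  op1 <- op[!duplicated(op$person_id), ]
  oidx <- match(dx$person_id, op1$person_id)
  within <- !is.na(oidx) & !is.na(dx$exposure_date) &
    dx$exposure_date >= op1$start_date[oidx] &
    dx$exposure_date <= op1$end_date[oidx]
  outside <- which(!is.na(oidx) & !is.na(dx$exposure_date) & !within)
  for (i in outside) {
    add("drug_exposure", i,
        paste0("exposure_date outside observation period for person_id ",
               dx$person_id[i]))
  }
  bidx <- match(dx$person_id, p$person_id)
  early <- which(!is.na(bidx) & !is.na(dx$exposure_date) &
                   dx$exposure_date < p$birth_date[bidx])
  for (i in early) add("drug_exposure", i, "exposure_date before birth_date")
  cbidx <- match(co$person_id, p$person_id)
  cearly <- which(!is.na(cbidx) & !is.na(co$condition_start_date) &
                    co$condition_start_date < p$birth_date[cbidx])
  for (i in cearly) add("condition_occurrence", i, "event before birth_date")

  if (length(probs) == 0) {
    tibble::tibble(table = character(), row = integer(), problem = character())
  } else {
    dplyr::bind_rows(probs)
  }
}

#' Validate a CDM bundle, erroring on any problem
#'
#' @param tables A `cdm_tables` object.
#' @return The tables, invisibly, if valid; otherwise an error whose message
#'   lists every offending table/row.
#' @export
validate_cdm <- function(tables) {
  probs <- cdm_problems(tables)
  if (nrow(probs) > 0) {
    msg <- paste0(probs$table, ifelse(is.na(probs$row), "",
                                      paste0(" row ", probs$row)),
                  ": ", probs$problem)
    stop("CDM validation failed (", nrow(probs), " problem(s)):\n  ",
         paste(head(msg, 25), collapse = "\n  "),
         if (nrow(probs) > 25) "\n  ..." else "", call. = FALSE)
  }
  invisible(tables)
}

cdm_file_names <- c(person = "person.csv",
                    observation_period = "observation_period.csv",
                    drug_exposure = "drug_exposure.csv",
                    condition_occurrence = "condition_occurrence.csv",
                    concept = "concept.csv")

cdm_col_types <- list(
  person = readr::cols(person_id = readr::col_integer(),
                       sex = readr::col_character(),
                       birth_date = readr::col_date()),
  observation_period = readr::cols(person_id = readr::col_integer(),
                                   start_date = readr::col_date(),
                                   end_date = readr::col_date()),
  drug_exposure = readr::cols(person_id = readr::col_integer(),
                              drug_concept_id = readr::col_integer(),
                              exposure_date = readr::col_date()),
  condition_occurrence = readr::cols(person_id = readr::col_integer(),
                                     condition_concept_id = readr::col_integer(),
                                     condition_start_date = readr::col_date()),
  concept = readr::cols(concept_id = readr::col_integer(),
                        concept_name = readr::col_character(),
                        domain = readr::col_character(),
                        drug_class = readr::col_character(),
                        condition_group = readr::col_character(),
                        syndrome_tag = readr::col_character())
)

#' Read a CDM bundle from a directory of CSV files
#'
#' Expects `person.csv`, `observation_period.csv`, `drug_exposure.csv`,
#' `condition_occurrence.csv` and `concept.csv` (comma-separated, UTF-8,
#' header row, ISO-8601 dates). The result is validated before return.
#'
#' @param path Directory containing the five files.
#' @param validate Validate after reading (default TRUE).
#' @return A `cdm_tables` object.
#' @export
read_cdm <- function(path, validate = TRUE) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  missing <- cdm_file_names[!file.exists(file.path(path, cdm_file_names))]
  if (length(missing) > 0) {
    stop("missing CDM file(s) in ", path, ": ",
         paste(names(missing), collapse = ", "), call. = FALSE)
  }
  tabs <- lapply(names(cdm_file_names), function(nm) {
    f <- file.path(path, cdm_file_names[[nm]])
    x <- readr::read_csv(f, col_types = cdm_col_types[[nm]],
                         progress = FALSE, show_col_types = FALSE)
    pr <- readr::problems(x)
    if (nrow(pr) > 0) {
      stop("unparseable value(s) in ", cdm_file_names[[nm]], " (row ",
           paste(unique(pr$row), collapse = ", "), ")", call. = FALSE)
    }
    x
  })
  names(tabs) <- names(cdm_file_names)
  cdm_tables(tabs$person, tabs$observation_period, tabs$drug_exposure,
             tabs$condition_occurrence, tabs$concept, validate = validate)
}

#' Write a CDM bundle to a directory of CSV files
#'
#' Inverse of [read_cdm()]: `read_cdm(write_cdm(t, d))` reproduces `t`
#' field-for-field (ISO-8601 dates, UTF-8, header rows).
#'
#' @param tables A validated `cdm_tables` object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_cdm <- function(tables, path) {
  validate_cdm(tables)
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  for (nm in names(cdm_file_names)) {
    readr::write_csv(tables[[nm]], file.path(path, cdm_file_names[[nm]]),
                     progress = FALSE)
  }
  invisible(path)
}
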