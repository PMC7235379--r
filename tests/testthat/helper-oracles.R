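# Independent brute-force re-implementations used as oracles.
# Deliberately naive: nested loops over rows, no joins, no indexing, no
# shared code with the package internals.

oracle_asm_ids <- function(tables) {
  ids <- integer(0)
  for (i in seq_len(nrow(tables$concept))) {
    dc <- tables$concept$drug_class[i]
    if (!is.na(dc) && dc == "N03A_ingredient") {
      ids <- c(ids, tables$concept$concept_id[i])
    }
  }
  ids
}

oracle_build_cohort <- function(tables, definition = cohort_definition()) {
  asm <- oracle_asm_ids(tables)
  rows <- list()
  for (i in seq_len(nrow(tables$person))) {
    pid <- tables$person$person_id[i]
    birth <- tables$person$birth_date[i]
    days <- as.Date(character(0))
    for (j in seq_len(nrow(tables$drug_exposure))) {
      if (tables$drug_exposure$person_id[j] == pid &&
          tables$drug_exposure$drug_concept_id[j] %in% asm) {
        days <- c(days, tables$drug_exposure$exposure_date[j])
      }
    }
    if (length(days) == 0) next
    idx <- min(days)
    age <- as.numeric(idx - birth) / 365.25
    if (age > definition$max_index_age_years) next
    ok_obs <- FALSE; fup <- NA_integer_
    for (j in seq_len(nrow(tables$observation_period))) {
      if (tables$observation_period$person_id[j] == pid) {
        s <- tables$observation_period$start_date[j]
        e <- tables$observation_period$end_date[j]
        fup <- as.integer(e - idx)
        if (s <= idx && fup >= definition$min_post_index_days) ok_obs <- TRUE
      }
    }
    if (!ok_obs) next
    if (definition$require_diagnosis) {
      has <- FALSE
      for (j in seq_len(nrow(tables$condition_occurrence))) {
        if (tables$condition_occurrence$person_id[j] == pid) has <- TRUE
      }
      if (!has) next
    }
    offs <- as.integer(days - idx)
    pass <- TRUE
    for (w in definition$persistence_windows) {
      hit <- FALSE
      for (o in offs) if (o >= w[1] && o <= w[2]) hit <- TRUE
      if (!hit) { pass <- FALSE; break }
    }
    if (!pass) next
    rows[[length(rows) + 1L]] <- data.frame(
      person_id = pid, index_date = idx, age_at_index = age,
      followup_days = fup)
  }
  if (length(rows) == 0) {
    return(data.frame(person_id = integer(), index_date = as.Date(character()),
                      age_at_index = numeric(), followup_days = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(out$person_id), , drop = FALSE]
}

# first-appearance-ordered distinct ingredients within [0, window] days
oracle_sequence <- function(index_date, drug_ids, dates, window = 730,
                            cap = 20) {
  ord <- order(dates, drug_ids)
  seen <- integer(0)
  for (k in ord) {
    off <- as.integer(dates[k] - index_date)
    if (off < 0 || (!is.null(window) && off > window)) next
    if (!drug_ids[k] %in% seen) seen <- c(seen, drug_ids[k])
  }
  seen[seq_len(min(length(seen), cap))]
}

oracle_count_pathways <- function(seq_strings) {
  u <- unique(seq_strings)
  n <- integer(length(u))
  for (i in seq_along(u)) {
    for (s in seq_strings) if (s == u[i]) n[i] <- n[i] + 1L
  }
  out <- data.frame(sequence = u, n_patients = n)
  out[order(-out$n_patients, out$sequence), , drop = FALSE]
}

oracle_dre <- function(n_distinct, threshold = 3) n_distinct >= threshold

# random small synthetic instance (shared by equivalence tests)
random_instance <- function(seed, n = NULL) {
  if (is.null(n)) n <- sample(3:60, 1)
  cfg <- generator_config(n_patients = n, seed = seed,
                          p_dropout = runif(1, 0, 0.5))
  generate_cdm(cfg)
}

# directly fabricate a sequences tibble (bypasses the pipeline) for
# property tests over the summarizing operations
random_sequences_tbl <- function(n_patients, n_drugs = 6) {
  drugs <- paste0("drug", seq_len(n_drugs))
  rows <- lapply(seq_len(n_patients), function(i) {
    len <- sample(1:min(5, n_drugs), 1)
    ing <- sample(drugs, len)
    tibble::tibble(person_id = i, ingredients = list(ing),
                   sequence = paste(ing, collapse = "\u2192"),
                   n_distinct = len, is_dre = len >= 3)
  })
  if (n_patients == 0) {
    return(tibble::tibble(person_id = integer(), ingredients = list(),
                          sequence = character(), n_distinct = integer(),
                          is_dre = logical()))
  }
  dplyr::bind_rows(rows)
}
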