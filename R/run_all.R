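#' Pipeline run configuration
#'
#' Collects every knob of an end-to-end run so a run is reproducible from
#' the config plus the input directory. Serializable with
#' [jsonlite::toJSON()] (the cohort definition is stored as its parts).
#'
#' @param definition A [cohort_definition()].
#' @param window_days Sequencing window (days after index); default 730.
#' @param cap Maximum sequence length; default 20.
#' @param dre_threshold Distinct-ASM count defining drug resistance.
#' @param strat_kinds Stratification kinds to run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(definition = cohort_definition(), window_days = 730L,
                       cap = 20L, dre_threshold = 3L,
                       strat_kinds = c("epilepsy_type", "onset_age", "syndrome")) {
  stopifnot(inherits(definition, "cohort_definition"),
            all(strat_kinds %in% c("epilepsy_type", "onset_age",
                                   "syndrome", "all")))
  structure(list(definition = definition, window_days = window_days,
                 cap = cap, dre_threshold = dre_threshold,
                 strat_kinds = strat_kinds),
            class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
}

pathway_table_df <- function(pt) {
  tibble::tibble(sequence = pt$sequence, n_patients = pt$n_patients)
}

#' Run the full treatment-pathway pipeline
#'
#' Executes validate -> build_cohort -> sequences -> pathways -> strata ->
#' annual trend on a CDM directory and writes all outputs: `cohort.csv`,
#' `exclusions.csv`, `pathways.csv`, `dist.json`, `sunburst.json`,
#' `strata/<kind>.csv`, `trend.csv` and a human-readable `summary.txt`
#' (cohort size, number of distinct pathways, top-5 ingredient shares,
#' ASM-count distribution, per-stratum DRE percentages). One log line per
#' stage reports input/output row counts, which makes the inclusion
#' cascade auditable. Output is deterministic: two runs on the same inputs
#' and config are byte-identical.
#'
#' @param cdm_dir Directory with the five CDM CSV files.
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param quiet Suppress stage log lines (default FALSE).
#' @return Invisibly, a list with `cohort`, `sequences`, `pathways`,
#'   `distribution`, `frequency`, `strata`, `trend`, `sunburst`.
#' @export
run_all <- function(cdm_dir, out_dir, config = run_config(), quiet = FALSE) {
  log_line <- function(...) if (!quiet) message("[epipathways] ", sprintf(...))
  if (!dir.exists(cdm_dir)) {
    stop("input directory not found: ", cdm_dir, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  tables <- read_cdm(cdm_dir)
  log_line("validate: %d persons, %d exposures, %d conditions",
           nrow(tables$person), nrow(tables$drug_exposure),
           nrow(tables$condition_occurrence))

  cohort <- build_cohort(tables, config$definition)
  excl <- cohort_exclusions(tables, config$definition)
  log_line("build_cohort: %d of %d persons admitted", nrow(cohort),
           nrow(tables$person))
  readr::write_csv(cohort, file.path(out_dir, "cohort.csv"), progress = FALSE)
  readr::write_csv(excl, file.path(out_dir, "exclusions.csv"), progress = FALSE)

  sequences <- build_sequences(tables, cohort, window_days = config$window_days,
                               cap = config$cap,
                               dre_threshold = config$dre_threshold)
  log_line("sequences: %d members sequenced", nrow(sequences))

  pathways <- count_pathways(sequences)
  log_line("pathways: %d distinct pathways", nrow(pathways))
  readr::write_csv(pathway_table_df(pathways),
                   file.path(out_dir, "pathways.csv"), progress = FALSE)

  dist <- asm_count_distribution(sequences)
  freq <- asm_frequency(sequences)
  write_json_file(list(
    total_patients = nrow(sequences),
    counts = setNames(as.list(dist$n), dist$n_asm),
    percentages = setNames(as.list(dist$pct), dist$n_asm),
    dre_pct = if (nrow(sequences) == 0) NA_real_
              else round(100 * mean(sequences$is_dre), 1)),
    file.path(out_dir, "dist.json"))

  sunburst <- pathway_to_sunburst(pathways)
  write_json_file(sunburst, file.path(out_dir, "sunburst.json"))

  strata <- list()
  if (length(config$strat_kinds) > 0) {
    dir.create(file.path(out_dir, "strata"), showWarnings = FALSE)
    for (kind in config$strat_kinds) {
      st <- stratified_pathways(tables, cohort, sequences, kind)
      strata[[kind]] <- st
      df <- dplyr::bind_rows(lapply(names(st), function(nm) {
        d <- st[[nm]]$distribution
        tibble::tibble(stratum = nm, n_members = st[[nm]]$n_members,
                       n_pathways = nrow(st[[nm]]$pathways),
                       pct_1 = d$pct[1], pct_2 = d$pct[2], pct_3plus = d$pct[3],
                       dre_pct = st[[nm]]$dre_pct)
      }))
      readr::write_csv(df, file.path(out_dir, "strata",
                                     paste0(kind, ".csv")), progress = FALSE)
      log_line("stratify[%s]: %d strata", kind, length(st))
    }
  }

  trend <- annual_monotherapy_trend(tables, cohort)
  readr::write_csv(trend, file.path(out_dir, "trend.csv"), progress = FALSE)
  log_line("trend: %d year-ingredient rows", nrow(trend))

  summary_lines <- c(
    "epipathways run summary",
    "=======================",
    sprintf("persons in input:        %d", nrow(tables$person)),
    sprintf("cohort size:             %d", nrow(cohort)),
    sprintf("distinct pathways:       %d", nrow(pathways)),
    "",
    "ASM count distribution (distinct ingredients in window):")
  for (i in seq_len(nrow(dist))) {
    summary_lines <- c(summary_lines,
      sprintf("  %-3s %6d  (%s%%)", dist$n_asm[i], dist$n[i],
              formatC(dist$pct[i], format = "f", digits = 1)))
  }
  summary_lines <- c(summary_lines, "",
    sprintf("drug-resistant (>= %d ASMs): %s%%", config$dre_threshold,
            if (nrow(sequences) == 0) "NA"
            else formatC(100 * mean(sequences$is_dre), format = "f", digits = 1)),
    "", "top 5 ingredients by slot share:")
  for (i in seq_len(min(5, nrow(freq)))) {
    summary_lines <- c(summary_lines,
      sprintf("  %-16s %s%%", freq$ingredient[i],
              formatC(100 * freq$share[i], format = "f", digits = 1)))
  }
  for (kind in names(strata)) {
    summary_lines <- c(summary_lines, "", sprintf("DRE%% by %s:", kind))
    for (nm in names(strata[[kind]])) {
      summary_lines <- c(summary_lines,
        sprintf("  %-14s n=%-6d DRE=%s%%", nm, strata[[kind]][[nm]]$n_members,
                ifelse(is.na(strata[[kind]][[nm]]$dre_pct), "NA",
                       formatC(strata[[kind]][[nm]]$dre_pct,
                               format = "f", digits = 1))))
    }
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  log_line("summary written to %s", file.path(out_dir, "summary.txt"))

  invisible(list(cohort = cohort, sequences = sequences, pathways = pathways,
                 distribution = dist, frequency = freq, strata = strata,
                 trend = trend, sunburst = sunburst))
}
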