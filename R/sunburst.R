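#' Convert a pathway table to a sunburst hierarchy
#'
#' Aggregates the sequences into a prefix tree: each node carries an
#' ingredient name and the number of patients whose pathway passes through
#' that prefix; the root carries the cohort size. Patients whose pathway
#' ends at a node account for the difference between the node's count and
#' its children's sum, so the hierarchy is lossless —
#' [sunburst_to_pathways()] reconstructs the table exactly. Children are
#' ordered by descending count then name. The nested list serializes
#' directly to the name/n_patients/children JSON consumed by common
#' sunburst renderers; no plotting is done here.
#'
#' @param table A `pathway_table` from [count_pathways()].
#' @return Nested list: `list(name = "root", n_patients = total, children = ...)`.
#' @export
pathway_to_sunburst <- function(table) {
  build <- function(name, seqs, counts) {
    n <- sum(counts)
    nonempty <- lengths(seqs) > 0
    children <- list()
    if (any(nonempty)) {
      firsts <- vapply(seqs[nonempty], function(s) s[1], "")
      for (f in unique(firsts)) {
        sel <- which(nonempty)[firsts == f]
        children[[length(children) + 1L]] <-
          build(f, lapply(seqs[sel], function(s) s[-1]), counts[sel])
      }
      ord <- order(-vapply(children, function(c) c$n_patients, numeric(1)),
                   vapply(children, function(c) c$name, ""))
      children <- children[ord]
    }
    list(name = name, n_patients = as.integer(n), children = children)
  }
  build("root", table$ingredients, table$n_patients)
}

#' Reconstruct a pathway table from a sunburst hierarchy
#'
#' Exact inverse of [pathway_to_sunburst()]: a node whose count exceeds the
#' sum of its children's counts contributes that many patients whose
#' pathway ends at the node.
#'
#' @param node A sunburst node list (usually the root).
#' @return A `pathway_table` equal to the one the hierarchy was built from.
#' @export
sunburst_to_pathways <- function(node) {
  rows <- list()
  walk <- function(n, prefix) {
    child_sum <- sum(vapply(n$children, function(c) c$n_patients, numeric(1)))
    terminal <- n$n_patients - child_sum
    if (terminal > 0 && length(prefix) > 0) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        sequence = paste(prefix, collapse = "\u2192"),
        ingredients = list(prefix), n_patients = as.integer(terminal))
    }
    for (c in n$children) walk(c, c(prefix, c$name))
  }
  walk(node, character(0))
  out <- if (length(rows) == 0) {
    tibble::tibble(sequence = character(), ingredients = list(),
                   n_patients = integer())
  } else {
    dplyr::arrange(dplyr::bind_rows(rows),
                   dplyr::desc(.data$n_patients), .data$sequence)
  }
  attr(out, "total_patients") <- as.integer(node$n_patients)
  class(out) <- c("pathway_table", class(out))
  out
}
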