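#' Protein-level co-regulation across PTM layers
#'
#' Joins phosphorylation and di-Gly (ubiquitylation) regulation calls —
#' and optionally interactor calls — at the protein level. A protein
#' appears in the output when it carries at least one up-regulated site
#' (at either time point) in either PTM layer; it is co-regulated when it
#' carries up-regulated phosphorylation *and* up-regulated ubiquitylation.
#' The result is invariant to the order of the input call lists.
#'
#' @param phospho_calls,digly_calls `regulation_calls` data.frames.
#' @param interactor_calls Optional `interactor_calls` data.frame used to
#'   flag signalosome membership.
#' @return A data.frame of class `coregulation_records`, sorted by
#'   `Protein.ID`: `Protein.ID`, `n_up_phospho_sites`, `n_up_digly_sites`,
#'   `has_up_phospho`, `has_up_digly`, `in_signalosome`, `co_regulated`.
#' @export
co_regulated_proteins <- function(phospho_calls, digly_calls,
                                  interactor_calls = NULL) {
  up_counts <- function(calls) {
    up <- calls$class_5min == "up" | calls$class_15min == "up"
    counts <- table(calls$Protein.ID[up])
    stats::setNames(as.integer(counts), names(counts))
  }
  up_p <- up_counts(phospho_calls)
  up_d <- up_counts(digly_calls)
  ids <- as.character(sort(unique(c(names(up_p), names(up_d)))))
  n_p <- ifelse(ids %in% names(up_p), up_p[ids], 0L)
  n_d <- ifelse(ids %in% names(up_d), up_d[ids], 0L)
  in_sig <- rep(FALSE, length(ids))
  if (!is.null(interactor_calls)) {
    sig_ids <- interactor_calls$Protein.ID[interactor_calls$interactor]
    in_sig <- ids %in% sig_ids
  }
  out <- data.frame(
    Protein.ID = ids,
    n_up_phospho_sites = as.integer(n_p),
    n_up_digly_sites = as.integer(n_d),
    has_up_phospho = n_p > 0L,
    has_up_digly = n_d > 0L,
    in_signalosome = in_sig,
    co_regulated = n_p > 0L & n_d > 0L,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("coregulation_records", "data.frame")
  out
}

#' @export
print.coregulation_records <- function(x, ...) {
  cat(sprintf(
    "PTM co-regulation: %d proteins with an up-regulated site; %d co-regulated (phospho + di-Gly)\n",
    nrow(x), sum(x$co_regulated)))
  NextMethod()
}

#' Hypergeometric annotation-term enrichment
#'
#' Generic over-representation test for annotation terms (e.g. Gene
#' Ontology) in a study set of proteins against a universe. For a term
#' annotating K of the N universe proteins, with k hits among the n study
#' proteins, the one-sided upper-tail hypergeometric p-value is
#' P(X >= k). Benjamini-Hochberg q-values are computed across the tested
#' terms; terms with no study hit (k = 0) are skipped. The universe should
#' normally be the proteins quantified in the relevant layer, not the
#' whole proteome.
#'
#' @param study_set Character vector of protein IDs (must be a subset of
#'   `universe`; duplicates ignored).
#' @param annotation_map Either a named list of character vectors
#'   (term -> protein IDs) or a two-column data.frame `(term, protein_id)`.
#' @param universe Character vector of protein IDs defining the test
#'   universe.
#' @param adjust_over `"tested"` (default, BH across terms with k >= 1) or
#'   `"all"` (BH counting every term with K >= 1 in the family).
#' @return A data.frame of class `enrichment_results`, one row per tested
#'   term, sorted by p-value: `term`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`.
#' @examples
#' ann <- list(kinase = c("P1", "P2", "P3"), other = c("P4", "P5"))
#' hypergeometric_enrichment(c("P1", "P2"), ann, paste0("P", 1:10))
#' @export
hypergeometric_enrichment <- function(study_set, annotation_map, universe,
                                      adjust_over = c("tested", "all")) {
  adjust_over <- match.arg(adjust_over)
  universe <- unique(as.character(universe))
  study_set <- unique(as.character(study_set))
  outside <- setdiff(study_set, universe)
  if (length(outside))
    .stop("silacsig_validation_error",
          "study protein(s) absent from universe: %s",
          paste(utils::head(outside, 5), collapse = ", "))
  if (is.data.frame(annotation_map)) {
    annotation_map <- split(as.character(annotation_map[[2]]),
                            as.character(annotation_map[[1]]))
  }
  N <- length(universe)
  n <- length(study_set)
  terms <- sort(names(annotation_map))
  rows <- lapply(terms, function(term) {
    ann <- intersect(unique(as.character(annotation_map[[term]])), universe)
    K <- length(ann)
    k <- length(intersect(ann, study_set))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p_value = if (k > 0) stats::phyper(k - 1, K, N - K, n,
                                                  lower.tail = FALSE)
                         else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  m_all <- sum(res$K >= 1)
  res <- res[res$k >= 1, , drop = FALSE]
  if (nrow(res)) {
    m <- if (adjust_over == "all") m_all else nrow(res)
    res$q_value <- pmin(1, stats::p.adjust(res$p_value, method = "BH",
                                           n = m))
    res <- res[order(res$p_value, res$term), , drop = FALSE]
    row.names(res) <- NULL
  } else {
    res$q_value <- numeric(0)
  }
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' @export
print.enrichment_results <- function(x, ...) {
  cat(sprintf("Term enrichment: %d tested term(s), %d with q < 0.05\n",
              nrow(x), sum(x$q_value < 0.05)))
  NextMethod()
}

#' Export a node-attribute edge list for network tools
#'
#' Writes a deterministic two-column (plus flags) TSV loadable by standard
#' network tools, linking each protein to its category: for interactor
#' calls the time-point membership (`both`, `5min`, `15min`), for
#' co-regulation records the PTM layers involved. Rows are sorted by
#' protein ID; an empty input yields a header-only file.
#'
#' @param x An `interactor_calls` or `coregulation_records` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_edge_list <- function(x, path) {
  if (inherits(x, "interactor_calls")) {
    x <- x[x$interactor, , drop = FALSE]
    attribute <- ifelse(x$enriched_5min & x$enriched_15min, "both",
                        ifelse(x$enriched_5min, "5min", "15min"))
    out <- data.frame(protein_id = x$Protein.ID, attribute = attribute,
                      stringsAsFactors = FALSE)
  } else if (inherits(x, "coregulation_records")) {
    attribute <- ifelse(x$co_regulated, "phospho+diGly",
                        ifelse(x$has_up_phospho, "phospho", "diGly"))
    out <- data.frame(protein_id = x$Protein.ID, attribute = attribute,
                      stringsAsFactors = FALSE)
  } else {
    .stop("silacsig_validation_error",
          "export_edge_list() expects interactor_calls or coregulation_records")
  }
  out <- out[order(out$protein_id), , drop = FALSE]
  row.names(out) <- NULL
  .write_tsv(out, path)
}
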