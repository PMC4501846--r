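#' Confidence thresholds for PTM-site identification
#'
#' The defaults are the standard high-confidence filter for MaxQuant site
#' tables: localization probability >= 0.75, identification (Andromeda)
#' score >= 40, posterior error probability (PEP) <= 0.01. All three
#' boundaries are inclusive.
#'
#' @param min_localization_prob Minimum site localization probability.
#' @param min_score Minimum identification score.
#' @param max_pep Maximum posterior error probability.
#' @return An object of class `quality_thresholds`.
#' @export
quality_thresholds <- function(min_localization_prob = 0.75,
                               min_score = 40,
                               max_pep = 0.01) {
  .check_proportion(min_localization_prob, "min_localization_prob")
  if (!is.finite(min_score)) .stop("silacsig_config_error",
                                   "'min_score' must be finite")
  .check_proportion(max_pep, "max_pep")
  structure(list(min_localization_prob = min_localization_prob,
                 min_score = min_score, max_pep = max_pep),
            class = "quality_thresholds")
}

#' @export
print.quality_thresholds <- function(x, ...) {
  cat(sprintf(
    "Site confidence filter: localization >= %g, score >= %g, PEP <= %g\n",
    x$min_localization_prob, x$min_score, x$max_pep))
  invisible(x)
}

#' Filter PTM sites on identification confidence
#'
#' Keeps a site iff `Localization.prob >= min_localization_prob` AND
#' `Score >= min_score` AND `PEP <= max_pep` (boundaries inclusive). A
#' missing quality value fails its criterion. The rejection log records the
#' first criterion each rejected site failed, in the order localization,
#' score, PEP; the filters are idempotent and mutually order-independent,
#' and kept plus rejected partition the input.
#'
#' @param sites A `ptm_sites` table (see [read_ptm_sites()]).
#' @param thresholds A [quality_thresholds()] object.
#' @return A list with elements `kept` (a `ptm_sites` table) and
#'   `rejected` (the rejected rows plus a `reason` column).
#' @export
filter_confident_sites <- function(sites, thresholds = quality_thresholds()) {
  stopifnot(inherits(thresholds, "quality_thresholds"))
  loc_ok <- !is.na(sites$Localization.prob) &
    sites$Localization.prob >= thresholds$min_localization_prob
  score_ok <- !is.na(sites$Score) & sites$Score >= thresholds$min_score
  pep_ok <- !is.na(sites$PEP) & sites$PEP <= thresholds$max_pep
  reason <- rep(NA_character_, nrow(sites))
  reason[!pep_ok] <- "pep"
  reason[!score_ok] <- "score"
  reason[!loc_ok] <- "localization_prob"   # first-listed criterion wins
  keep <- loc_ok & score_ok & pep_ok
  rejected <- sites[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = sites[keep, , drop = FALSE], rejected = rejected)
}

#' Require di-Gly sites to be internal to their peptide
#'
#' Drops di-Gly (ubiquitylation remnant) sites whose modified lysine is the
#' peptide C-terminus. Trypsin does not cleave after a di-Gly-modified
#' lysine, so a peptide ending in a modified lysine is an identification
#' artifact rather than a genuine ubiquitylation site. Passing
#' phosphorylation records is a contract violation and raises an error.
#'
#' @param sites A `ptm_sites` table whose rows are all di-Gly sites.
#' @return A list with elements `kept` and `rejected` (with a `reason`
#'   column, always `"peptide_cterm"`).
#' @export
require_internal_digly <- function(sites) {
  if (any(sites$Modification != "diGly"))
    .stop("silacsig_validation_error",
          "require_internal_digly() accepts di-Gly sites only")
  keep <- !.as_logical(sites$Peptide.Cterm)
  rejected <- sites[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- "peptide_cterm"
  else rejected$reason <- character(0)
  list(kept = sites[keep, , drop = FALSE], rejected = rejected)
}

#' Write a rejection log
#'
#' @param rejected The `rejected` element returned by a site filter.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_log <- function(rejected, path) .write_tsv(rejected, path)
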