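#' Read a protein-group SILAC ratio table
#'
#' Reads a tab-separated protein-group table in the package's fixed
#' MaxQuant-like dialect. Mandatory columns are `Protein.ID` and at least
#' one pair of per-replicate ratio columns `Ratio.M.L.rep{k}` /
#' `Ratio.H.L.rep{k}`; `Gene.name` and `N.peptides` are optional. Ratios are
#' linear-scale and strictly positive; empty cells, `NA` and `NaN` denote
#' missing values and are never coerced to zero. No filtering happens at
#' read time.
#'
#' @param path Path to a TSV file (UTF-8, `.` decimal separator).
#' @param col_map Optional named character vector mapping dialect column
#'   names to the names actually present in the file, e.g.
#'   `c(Protein.ID = "Majority protein IDs")`. Used to ingest real MaxQuant
#'   exports without rewriting them.
#' @return A `data.frame` of class `protein_groups`, one row per protein
#'   group, in file order.
#' @seealso [write_protein_groups()], [read_ptm_sites()]
#' @export
read_protein_groups <- function(path, col_map = NULL) {
  df <- .read_tsv(path, col_map)
  validate_protein_groups(df)
}

#' Validate an in-memory protein-group table
#'
#' @param df A data.frame in the dialect of [read_protein_groups()].
#' @return The validated table, classed `protein_groups`.
#' @export
validate_protein_groups <- function(df) {
  .require_cols(df, "Protein.ID")
  ml <- .ratio_cols(df, "ML")
  hl <- .ratio_cols(df, "HL")
  if (length(ml) + length(hl) == 0L)
    .stop("silacsig_format_error",
          "no ratio columns ('Ratio.M.L.rep*' / 'Ratio.H.L.rep*') present")
  .check_positive_ratios(df, c(ml, hl))
  class(df) <- c("protein_groups", "data.frame")
  df
}

#' Read a PTM-site SILAC ratio table
#'
#' Reads a tab-separated table of modified sites (phosphorylation or
#' di-Gly/ubiquitylation) in the package's fixed dialect. Beyond the
#' protein-group columns, site tables carry `Residue` (one of S, T, Y, K),
#' `Position` (1-based on the protein), `Modification` (`phospho` or
#' `diGly`), `Localization.prob` and `PEP` (both in \[0, 1\]), `Score`, and
#' `Peptide.Cterm` (logical; whether the modified residue is the peptide
#' C-terminus, meaningful for di-Gly sites). Residue/modification
#' consistency is enforced: lysine iff di-Gly. Quality filtering is *not*
#' applied here; see [filter_confident_sites()].
#'
#' @inheritParams read_protein_groups
#' @param modification Expected modification, `"phospho"` or `"diGly"`;
#'   rows with a different `Modification` value raise a validation error.
#' @return A `data.frame` of class `ptm_sites`, one row per site, in file
#'   order.
#' @export
read_ptm_sites <- function(path, modification = c("phospho", "diGly"),
                           col_map = NULL) {
  modification <- match.arg(modification)
  df <- .read_tsv(path, col_map)
  validate_ptm_sites(df, modification)
}

#' Validate an in-memory PTM-site table
#'
#' @param df A data.frame in the dialect of [read_ptm_sites()].
#' @param modification Expected modification for every row.
#' @return The validated table, classed `ptm_sites`.
#' @export
validate_ptm_sites <- function(df, modification = c("phospho", "diGly")) {
  modification <- match.arg(modification)
  .require_cols(df, c("Protein.ID", "Residue", "Position", "Modification",
                      "Localization.prob", "Score", "PEP"))
  if (length(.ratio_cols(df, "ML")) + length(.ratio_cols(df, "HL")) == 0L)
    .stop("silacsig_format_error",
          "no ratio columns ('Ratio.M.L.rep*' / 'Ratio.H.L.rep*') present")
  if (!"Peptide.Cterm" %in% names(df)) df$Peptide.Cterm <- FALSE
  df$Peptide.Cterm <- .as_logical(df$Peptide.Cterm)

  bad <- which(df$Modification != modification)
  if (length(bad))
    .stop("silacsig_validation_error",
          "row(s) %s: Modification is not '%s'",
          paste(bad, collapse = ", "), modification)
  expected <- if (modification == "diGly") "K" else c("S", "T", "Y")
  bad <- which(!df$Residue %in% expected)
  if (length(bad))
    .stop("silacsig_validation_error",
          "row(s) %s: residue not compatible with modification '%s' (%s)",
          paste(bad, collapse = ", "), modification,
          paste(expected, collapse = "/"))
  bad <- which(is.na(df$Position) | df$Position < 1 |
                 df$Position != round(df$Position))
  if (length(bad))
    .stop("silacsig_validation_error",
          "row(s) %s: Position must be a 1-based integer",
          paste(bad, collapse = ", "))
  for (col in c("Localization.prob", "PEP")) {
    bad <- which(!is.na(df[[col]]) & (df[[col]] < 0 | df[[col]] > 1))
    if (length(bad))
      .stop("silacsig_validation_error", "row(s) %s: %s outside [0, 1]",
            paste(bad, collapse = ", "), col)
  }
  .check_positive_ratios(df, c(.ratio_cols(df, "ML"), .ratio_cols(df, "HL")))
  class(df) <- c("ptm_sites", "data.frame")
  df
}

#' Write a protein-group or PTM-site table
#'
#' Writes the table back in the same TSV dialect the readers consume;
#' writing then reading reproduces the input. Missing ratios are written as
#' empty cells.
#'
#' @param x A `protein_groups` or `ptm_sites` table (or compatible
#'   data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_groups <- function(x, path) .write_tsv(x, path)

#' @rdname write_protein_groups
#' @export
write_ptm_sites <- function(x, path) .write_tsv(x, path)

#' Write classification calls as TSV
#'
#' Writes interactor or regulation call tables with a stable column order
#' (the order of the input data.frame). An empty call list yields a
#' header-only file.
#'
#' @param calls A data.frame of calls, e.g. from [call_interactors()] or
#'   [classify_regulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) .write_tsv(calls, path)

#' Read back a calls TSV written by [write_calls()]
#'
#' @param path Path to a calls TSV.
#' @return A data.frame.
#' @export
read_calls <- function(path) .read_tsv(path, NULL)

#' Write a summary report as canonical JSON
#'
#' Keys are sorted recursively, so re-serialising an unchanged report is
#' byte-identical. Numbers are written at full precision.
#'
#' @param report A named list (e.g. the result of [run_pipeline()]).
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  report <- .sort_keys(unclass(report))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

.sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x))
    x <- lapply(x[order(names(x))], .sort_keys)
  x
}

.read_tsv <- function(path, col_map) {
  if (!file.exists(path))
    .stop("silacsig_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA", "NaN"))
  if (!is.null(col_map)) {
    for (target in names(col_map)) {
      src <- col_map[[target]]
      if (!src %in% names(df))
        .stop("silacsig_format_error", "mapped column '%s' not in file", src)
      names(df)[names(df) == src] <- target
    }
  }
  df
}

.write_tsv <- function(x, path) {
  x <- as.data.frame(x)
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .stop("silacsig_io_error", "cannot write '%s': %s", path,
          conditionMessage(ok))
  invisible(path)
}

.require_cols <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    .stop("silacsig_format_error", "mandatory column(s) missing: %s",
          paste(missing, collapse = ", "))
  invisible(df)
}

.check_positive_ratios <- function(df, cols) {
  for (col in cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad))
      .stop("silacsig_validation_error",
            "row(s) %s: non-positive ratio in column '%s'",
            paste(bad, collapse = ", "), col)
  }
  invisible(df)
}

.as_logical <- function(v) {
  if (is.logical(v)) return(ifelse(is.na(v), FALSE, v))
  out <- toupper(trimws(as.character(v))) %in% c("TRUE", "T", "1", "YES")
  out
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("Protein-group SILAC table: %d proteins, %d replicate(s)\n",
              nrow(x), .n_replicates(x)))
  NextMethod()
}

#' @export
print.ptm_sites <- function(x, ...) {
  mod <- if (nrow(x)) unique(x$Modification) else "empty"
  cat(sprintf("PTM-site SILAC table (%s): %d sites, %d replicate(s)\n",
              paste(mod, collapse = ","), nrow(x), .n_replicates(x)))
  NextMethod()
}
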