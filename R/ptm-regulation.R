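#' Regulation thresholds for PTM sites
#'
#' A site counts as up-regulated at a time point when its linear SILAC
#' ratio is >= `up_fold` and down-regulated when <= `down_fold` (both
#' boundaries inclusive). The defaults, 2 and 0.5, are symmetric on the
#' log scale.
#'
#' @param up_fold Linear fold threshold for up-regulation (> 1).
#' @param down_fold Linear fold threshold for down-regulation (in (0, 1)).
#' @return An object of class `regulation_thresholds`.
#' @export
regulation_thresholds <- function(up_fold = 2.0, down_fold = 0.5) {
  if (!is.numeric(up_fold) || up_fold <= 1)
    .stop("silacsig_config_error", "'up_fold' must be > 1")
  if (!is.numeric(down_fold) || down_fold <= 0 || down_fold >= 1)
    .stop("silacsig_config_error", "'down_fold' must be in (0, 1)")
  structure(list(up_fold = up_fold, down_fold = down_fold),
            class = "regulation_thresholds")
}

#' @export
print.regulation_thresholds <- function(x, ...) {
  cat(sprintf("Regulation thresholds: up >= %g-fold, down <= %g-fold\n",
              x$up_fold, x$down_fold))
  invisible(x)
}

#' Call up/down regulation of PTM sites per time point
#'
#' For each site and channel, the per-site ratio is the median linear
#' ratio across replicates (missing replicates skipped). The class is
#' `up` when the ratio is >= `up_fold`, `down` when <= `down_fold`,
#' `unchanged` otherwise, and `missing` when no replicate is quantified in
#' that channel. A temporal dynamics label is attached via
#' [assign_dynamics_class()].
#'
#' @param sites A `ptm_sites` table, already confidence-filtered
#'   ([filter_confident_sites()]; for di-Gly additionally
#'   [require_internal_digly()]).
#' @param thresholds A [regulation_thresholds()] object.
#' @param transient_drop Passed to [assign_dynamics_class()].
#' @return A data.frame of class `regulation_calls`, one row per site:
#'   site key (`Protein.ID`, `Position`, `Residue`, `Modification`),
#'   `ratio_5min`, `ratio_15min` (median linear ratios), `class_5min`,
#'   `class_15min`, `dynamics`.
#' @export
classify_regulation <- function(sites, thresholds = regulation_thresholds(),
                                transient_drop = 2.0) {
  stopifnot(inherits(thresholds, "regulation_thresholds"))
  r5 <- 2^.median_log2(sites, "ML")
  r15 <- 2^.median_log2(sites, "HL")
  cls <- function(r) {
    out <- rep("unchanged", length(r))
    out[is.na(r)] <- "missing"
    out[!is.na(r) & r >= thresholds$up_fold] <- "up"
    out[!is.na(r) & r <= thresholds$down_fold] <- "down"
    out
  }
  c5 <- cls(r5)
  c15 <- cls(r15)
  out <- data.frame(
    Protein.ID = sites$Protein.ID,
    Position = sites$Position,
    Residue = sites$Residue,
    Modification = sites$Modification,
    ratio_5min = r5,
    ratio_15min = r15,
    class_5min = c5,
    class_15min = c15,
    dynamics = assign_dynamics_class(c5, c15, r5, r15, transient_drop),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Rule-based temporal dynamics classes
#'
#' Maps the pair of per-time-point regulation classes (plus the ratio drop
#' between time points) onto a deterministic dynamics label, replacing
#' unsupervised profile clustering:
#' \describe{
#'   \item{early-transient}{up at 5 min and either no longer up at 15 min
#'     or dropped by >= `transient_drop`-fold between the time points
#'     (e.g. an IkB-alpha-like site at 19.5-fold then 2-fold).}
#'   \item{sustained}{up at both time points with a drop <
#'     `transient_drop`-fold.}
#'   \item{late}{up only at 15 min (not up or down at 5 min).}
#'   \item{down-regulated}{down at either time point and up at neither.}
#'   \item{unregulated}{unchanged at both time points.}
#'   \item{mixed}{any remaining combination (down at 5 min but up at
#'     15 min).}
#' }
#' A `missing` class is treated as `unchanged` for the purpose of these
#' rules.
#'
#' @param class_5min,class_15min Character vectors of per-channel classes
#'   (`up`/`down`/`unchanged`/`missing`).
#' @param ratio_5min,ratio_15min Median linear ratios per channel.
#' @param transient_drop Minimum 5-min/15-min ratio fold drop for an
#'   up/up site to count as transient rather than sustained. Default 2.
#' @return Character vector of dynamics labels.
#' @export
assign_dynamics_class <- function(class_5min, class_15min,
                                  ratio_5min, ratio_15min,
                                  transient_drop = 2.0) {
  up5 <- class_5min == "up"
  up15 <- class_15min == "up"
  down5 <- class_5min == "down"
  down15 <- class_15min == "down"
  drop_ratio <- ratio_5min / ratio_15min
  big_drop <- !is.na(drop_ratio) & drop_ratio >= transient_drop
  out <- rep("mixed", length(class_5min))
  out[up5 & (!up15 | big_drop)] <- "early-transient"
  out[up5 & up15 & !big_drop] <- "sustained"
  out[!up5 & !down5 & up15] <- "late"
  out[(down5 | down15) & !up5 & !up15] <- "down-regulated"
  out[!up5 & !down5 & !up15 & !down15] <- "unregulated"
  out
}

#' @export
print.regulation_calls <- function(x, ...) {
  cat(sprintf(
    "Regulation calls: %d sites | 5 min: %d up, %d down | 15 min: %d up, %d down\n",
    nrow(x), sum(x$class_5min == "up"), sum(x$class_5min == "down"),
    sum(x$class_15min == "up"), sum(x$class_15min == "down")))
  NextMethod()
}

#' @export
summary.regulation_calls <- function(object, ...) {
  tab <- table(factor(object$dynamics,
                      levels = c("early-transient", "sustained", "late",
                                 "down-regulated", "unregulated", "mixed")))
  cat("Dynamics classes:\n")
  print(tab)
  invisible(tab)
}

#' Per-residue-class fold-change summary
#'
#' Summarises phosphorylation regulation by residue class (Tyr vs
#' Ser/Thr) and time point: the number of sites quantified, the number up-
#' and down-regulated, and the arithmetic mean linear fold change. By
#' default the mean is over all sites quantified at the time point
#' (`subset = "quantified"`); `subset = "up"` restricts it to up-regulated
#' sites.
#'
#' @param calls A `regulation_calls` data.frame from phosphorylation sites.
#' @param subset `"quantified"` (default) or `"up"`.
#' @return A data.frame with one row per (residue class, time point):
#'   `residue_class`, `timepoint`, `n_sites`, `n_up`, `n_down`,
#'   `mean_fold` (NA when no site enters the mean).
#' @export
residue_class_summary <- function(calls, subset = c("quantified", "up")) {
  subset <- match.arg(subset)
  rc <- ifelse(calls$Residue == "Y", "Tyr", "Ser/Thr")
  grid <- expand.grid(residue_class = c("Tyr", "Ser/Thr"),
                      timepoint = c("5min", "15min"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- grid$residue_class[i]
    tp <- grid$timepoint[i]
    ratio <- if (tp == "5min") calls$ratio_5min else calls$ratio_15min
    class <- if (tp == "5min") calls$class_5min else calls$class_15min
    sel <- rc == cl & !is.na(ratio)
    in_mean <- sel & (if (subset == "up") class == "up" else TRUE)
    data.frame(residue_class = cl, timepoint = tp,
               n_sites = sum(sel),
               n_up = sum(sel & class == "up"),
               n_down = sum(sel & class == "down"),
               mean_fold = if (any(in_mean)) mean(ratio[in_mean]) else
                 NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Compares two groups of values, e.g. log2 fold changes of Tyr vs
#' Ser/Thr phosphorylation sites. The exact null distribution is
#' enumerated when both groups have at most 8 observations and there are
#' no ties; otherwise the Normal approximation with tie correction and
#' continuity correction is used. Two-sided p-values under the exact
#' convention are the probability of a statistic at least as extreme,
#' doubled and capped at 1.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A list with `statistic` (the Mann-Whitney U of the first
#'   group), `p_value`, and `exact` (logical).
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact: 0.1
#' @export
ranksum_test <- function(values_a, values_b,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(values_a) == 0L || length(values_b) == 0L)
    .stop("silacsig_insufficient_data", "both groups must be non-empty")
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- !ties && length(values_a) <= 8L && length(values_b) <= 8L
  ht <- stats::wilcox.test(values_a, values_b, alternative = alternative,
                           exact = exact, correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}

#' Between-replicate Pearson correlation of log2 ratios
#'
#' @param records A `protein_groups` or `ptm_sites` table.
#' @param channel `"ML"` or `"HL"`.
#' @param rep_i,rep_j Replicate indices to compare.
#' @return Pearson correlation coefficient over entities quantified in
#'   both replicates (complete pairs); errors with fewer than 3 pairs.
#' @export
replicate_correlation <- function(records, channel = c("ML", "HL"),
                                  rep_i = 1, rep_j = 2) {
  channel <- match.arg(channel)
  m <- log2(.ratio_matrix(records, channel))
  cols <- paste0(.channel_prefix(channel), c(rep_i, rep_j))
  missing_cols <- setdiff(cols, colnames(m))
  if (length(missing_cols))
    .stop("silacsig_format_error", "replicate column(s) missing: %s",
          paste(missing_cols, collapse = ", "))
  x <- m[, cols[1]]
  y <- m[, cols[2]]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    .stop("silacsig_insufficient_data",
          "only %d complete pair(s) between replicates %d and %d; need >= 3",
          sum(ok), rep_i, rep_j)
  stats::cor(x[ok], y[ok])
}
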