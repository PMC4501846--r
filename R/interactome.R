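#' Fit the empirical background-binder model for one SILAC channel
#'
#' Affinity-purification experiments recover mostly background binders:
#' proteins that stick to the beads irrespective of the bait. The model
#' treats the `background_fraction` (default 90%) of proteins with the
#' lowest SILAC ratios as background and summarises the null distribution
#' of log2 ratios empirically. Each protein is summarised by the median of
#' its log2 ratios across replicates (missing replicates skipped); proteins
#' are sorted ascending by this summary (ties broken by `Protein.ID` for
#' determinism) and the lowest `floor(background_fraction * n)` form the
#' background set. The model records the median summary over *all*
#' quantified proteins and the sample standard deviation (n - 1
#' denominator) over the background set; the enrichment cutoff is
#' `median + sd_multiplier * SD` (see [derive_cutoffs()]).
#'
#' @param records A `protein_groups` table ([read_protein_groups()]).
#' @param channel `"ML"` (5 min / control) or `"HL"` (15 min / control).
#' @param background_fraction Fraction of proteins, lowest ratios first,
#'   treated as background binders. Default 0.90.
#' @return An object of class `silac_background` with fields `channel`,
#'   `median_log2` (median over all quantified proteins),
#'   `background_median_log2`, `sd_log2` (background sample SD),
#'   `n_background`, `n_quantified`, `background_fraction`, and the
#'   per-protein `summary_log2` vector used for the fit.
#' @examples
#' sim <- simulate_interactome(interactome_sim_config(n_proteins = 200,
#'                                                    seed = 1))
#' fit_background_model(sim$table, "ML")
#' @export
fit_background_model <- function(records, channel = c("ML", "HL"),
                                 background_fraction = 0.90) {
  channel <- match.arg(channel)
  .check_proportion(background_fraction, "background_fraction")
  summaries <- .median_log2(records, channel)
  names(summaries) <- records$Protein.ID
  summaries <- summaries[!is.na(summaries)]
  n_quant <- length(summaries)
  if (n_quant < 3L)
    .stop("silacsig_insufficient_data",
          "channel %s: %d quantified protein(s); need at least 3",
          channel, n_quant)
  n_background <- floor(background_fraction * n_quant)
  if (n_background < 2L)
    .stop("silacsig_insufficient_data",
          "channel %s: background set of size %d; need at least 2",
          channel, n_background)
  ord <- order(summaries, names(summaries))   # stable, deterministic
  background <- summaries[ord][seq_len(n_background)]
  structure(list(
    channel = channel,
    median_log2 = stats::median(summaries),
    background_median_log2 = stats::median(background),
    sd_log2 = stats::sd(background),
    n_background = n_background,
    n_quantified = n_quant,
    background_fraction = background_fraction,
    summary_log2 = summaries
  ), class = "silac_background")
}

#' @export
print.silac_background <- function(x, ...) {
  cat(sprintf(
    paste0("Empirical background model (channel %s)\n",
           "  quantified proteins : %d\n",
           "  background set      : %d (lowest %.0f%% of median log2 ratios)\n",
           "  median log2 (all)   : %.4f\n",
           "  background SD log2  : %.4f\n"),
    x$channel, x$n_quantified, x$n_background,
    100 * x$background_fraction, x$median_log2, x$sd_log2))
  invisible(x)
}

#' @export
coef.silac_background <- function(object, ...) {
  c(median_log2 = object$median_log2, sd_log2 = object$sd_log2)
}

#' @export
plot.silac_background <- function(x, sd_multiplier = 2, ...) {
  graphics::hist(x$summary_log2, breaks = 40, col = "grey85",
                 main = sprintf("Channel %s: per-protein median log2 ratios",
                                x$channel),
                 xlab = "median log2 SILAC ratio", ...)
  cutoff <- x$median_log2 + sd_multiplier * x$sd_log2
  graphics::abline(v = cutoff, col = "red", lwd = 2)
  graphics::mtext(sprintf("cutoff = median + %g SD = %.2f",
                          sd_multiplier, cutoff), col = "red", cex = 0.8)
  invisible(x)
}

#' Derive enrichment cutoffs from per-channel background models
#'
#' The cutoff for calling a protein enriched in a channel is
#' `median_log2 + sd_multiplier * sd_log2` of that channel's background
#' model (default multiplier 2, i.e. the classic median + 2SD rule).
#'
#' @param model_ml,model_hl `silac_background` models for the two channels.
#' @param sd_multiplier Number of background SDs above the median. Default 2.
#' @return An object of class `cutoff_set` with fields `cutoff_log2_ml`,
#'   `cutoff_log2_hl` and `sd_multiplier`.
#' @export
derive_cutoffs <- function(model_ml, model_hl, sd_multiplier = 2) {
  stopifnot(inherits(model_ml, "silac_background"),
            inherits(model_hl, "silac_background"))
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    .stop("silacsig_config_error", "'sd_multiplier' must be positive")
  structure(list(
    cutoff_log2_ml = model_ml$median_log2 + sd_multiplier * model_ml$sd_log2,
    cutoff_log2_hl = model_hl$median_log2 + sd_multiplier * model_hl$sd_log2,
    sd_multiplier = sd_multiplier
  ), class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf(
    "Enrichment cutoffs (median + %g SD): log2 M/L %.4f, log2 H/L %.4f\n",
    x$sd_multiplier, x$cutoff_log2_ml, x$cutoff_log2_hl))
  invisible(x)
}

#' Manually specify enrichment cutoffs
#'
#' @param cutoff_log2_ml,cutoff_log2_hl Log2-scale cutoffs per channel.
#' @return A `cutoff_set` object.
#' @export
cutoff_set <- function(cutoff_log2_ml, cutoff_log2_hl) {
  structure(list(cutoff_log2_ml = cutoff_log2_ml,
                 cutoff_log2_hl = cutoff_log2_hl,
                 sd_multiplier = NA_real_), class = "cutoff_set")
}

#' Call bait-specific interactors from replicate AP-MS SILAC tables
#'
#' A protein is called a signalosome-specific interactor when, in at least
#' one channel (time point), both criteria hold:
#' \enumerate{
#'   \item replicate support: a linear SILAC ratio >= `fold_threshold` in
#'     at least `min_replicates` replicates of that channel (boundary
#'     inclusive), and
#'   \item background cutoff: the protein's median log2 ratio across
#'     replicates is strictly greater than that channel's cutoff
#'     (median + 2SD of the empirical background by default).
#' }
#' The per-channel `enriched_5min` / `enriched_15min` flags require that
#' channel's own criteria (i) and (ii); overall interactor status is their
#' union. Proteins quantified in fewer than `min_replicates` replicates of
#' a channel cannot pass that channel. Down-enrichment is not called.
#'
#' @param records A `protein_groups` table.
#' @param cutoffs A `cutoff_set`, typically from [derive_cutoffs()].
#' @param min_replicates Minimum replicates supporting criterion (i).
#'   Default 2.
#' @param fold_threshold Linear-ratio threshold for criterion (i).
#'   Default 2.
#' @return A data.frame of class `interactor_calls` with one row per
#'   protein: `Protein.ID`, `median_log2_ml`, `median_log2_hl`,
#'   `support_5min`, `support_15min`, `enriched_5min`, `enriched_15min`,
#'   `interactor`.
#' @examples
#' sim <- simulate_interactome(interactome_sim_config(n_proteins = 300,
#'                                                    seed = 4))
#' bg_ml <- fit_background_model(sim$table, "ML")
#' bg_hl <- fit_background_model(sim$table, "HL")
#' calls <- call_interactors(sim$table, derive_cutoffs(bg_ml, bg_hl))
#' summary(calls)
#' @export
call_interactors <- function(records, cutoffs, min_replicates = 2,
                             fold_threshold = 2.0) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  min_replicates <- .check_count(min_replicates, "min_replicates")
  n_rep <- .n_replicates(records)
  if (nrow(records) > 0L && min_replicates > n_rep)
    .stop("silacsig_config_error",
          "min_replicates = %d exceeds the %d replicate(s) present",
          min_replicates, n_rep)
  if (nrow(records) == 0L) {
    out <- data.frame(Protein.ID = character(0), median_log2_ml = numeric(0),
                      median_log2_hl = numeric(0), support_5min = integer(0),
                      support_15min = integer(0), enriched_5min = logical(0),
                      enriched_15min = logical(0), interactor = logical(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("interactor_calls", "data.frame")
    return(out)
  }
  med_ml <- .median_log2(records, "ML")
  med_hl <- .median_log2(records, "HL")
  sup_ml <- .replicate_support(records, "ML", fold_threshold)
  sup_hl <- .replicate_support(records, "HL", fold_threshold)
  enr_ml <- sup_ml >= min_replicates & !is.na(med_ml) &
    med_ml > cutoffs$cutoff_log2_ml
  enr_hl <- sup_hl >= min_replicates & !is.na(med_hl) &
    med_hl > cutoffs$cutoff_log2_hl
  out <- data.frame(
    Protein.ID = records$Protein.ID,
    median_log2_ml = med_ml,
    median_log2_hl = med_hl,
    support_5min = as.integer(sup_ml),
    support_15min = as.integer(sup_hl),
    enriched_5min = enr_ml,
    enriched_15min = enr_hl,
    interactor = enr_ml | enr_hl,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("interactor_calls", "data.frame")
  out
}

#' @export
print.interactor_calls <- function(x, ...) {
  cat(sprintf("Interactor calls: %d proteins, %d called (%d at 5 min, %d at 15 min)\n",
              nrow(x), sum(x$interactor), sum(x$enriched_5min),
              sum(x$enriched_15min)))
  NextMethod()
}

#' @export
summary.interactor_calls <- function(object, ...) {
  venn <- partition_venn(object)
  cat(sprintf(
    paste0("Interactor calls over %d quantified proteins\n",
           "  enriched at both time points : %d\n",
           "  enriched at 5 min only       : %d\n",
           "  enriched at 15 min only      : %d\n",
           "  total interactors            : %d\n"),
    nrow(object), venn$n_both, venn$n_only_t1, venn$n_only_t2, venn$n_total))
  invisible(venn)
}

#' Partition interactor calls into a two-set Venn diagram
#'
#' Counts proteins enriched at both time points, only at 5 min, and only at
#' 15 min, among proteins with at least one enriched flag. The total is
#' always the sum of the three parts.
#'
#' @param calls An `interactor_calls` data.frame (or any data.frame with
#'   logical `enriched_5min` and `enriched_15min` columns).
#' @return An object of class `venn_partition` with fields `n_both`,
#'   `n_only_t1`, `n_only_t2`, `n_total`.
#' @export
partition_venn <- function(calls) {
  e5 <- calls$enriched_5min
  e15 <- calls$enriched_15min
  structure(list(
    n_both = sum(e5 & e15),
    n_only_t1 = sum(e5 & !e15),
    n_only_t2 = sum(!e5 & e15),
    n_total = sum(e5 | e15)
  ), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("Venn partition: both %d | 5 min only %d | 15 min only %d | total %d\n",
              x$n_both, x$n_only_t1, x$n_only_t2, x$n_total))
  invisible(x)
}

#' Expected null positive rate of the median + k*SD rule
#'
#' Closed-form asymptotic fraction of proteins exceeding the
#' median + `sd_multiplier` * SD cutoff when every protein is a background
#' binder with Gaussian log2 ratio summaries. Because the SD is computed on
#' the `background_fraction` of proteins with the lowest ratios, it is the
#' SD of a Normal truncated above at that quantile, which is smaller than
#' the full-sample SD; the exceedance mass is correspondingly larger than
#' the naive `1 - pnorm(sd_multiplier)`. For the defaults (90% background,
#' 2 SD) the rate is approximately 0.0457. The result is scale-invariant:
#' it does not depend on the background SD itself.
#'
#' @param background_fraction Fraction treated as background. Default 0.90.
#' @param sd_multiplier SD multiplier of the cutoff. Default 2.
#' @return The expected fraction of null proteins exceeding the cutoff.
#' @export
expected_null_positive_rate <- function(background_fraction = 0.90,
                                        sd_multiplier = 2) {
  b <- stats::qnorm(background_fraction)
  # mean and variance of N(0,1) truncated to (-Inf, b]
  m_t <- -stats::dnorm(b) / background_fraction
  v_t <- 1 - b * stats::dnorm(b) / background_fraction - m_t^2
  # overall median of the null is 0; cutoff = 0 + k * sd_truncated
  stats::pnorm(sd_multiplier * sqrt(v_t), lower.tail = FALSE)
}
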