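# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementation.

# Build a protein-group table from log2 ratio matrices (NA = missing).
make_pg <- function(log2_ml, log2_hl, ids = NULL) {
  n <- nrow(log2_ml)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  df <- data.frame(Protein.ID = ids, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(log2_ml)))
    df[[sprintf("Ratio.M.L.rep%d", k)]] <- 2^log2_ml[, k]
  for (k in seq_len(ncol(log2_hl)))
    df[[sprintf("Ratio.H.L.rep%d", k)]] <- 2^log2_hl[, k]
  df
}

# Build a minimal PTM site table.
make_sites <- function(ratio_5, ratio_15, residue = "S",
                       modification = "phospho",
                       loc = 0.99, score = 100, pep = 0.001,
                       cterm = FALSE, ids = NULL) {
  n <- length(ratio_5)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  data.frame(Protein.ID = ids,
             Residue = rep_len(residue, n),
             Position = seq_len(n) * 7L,
             Modification = modification,
             Localization.prob = rep_len(loc, n),
             Score = rep_len(score, n),
             PEP = rep_len(pep, n),
             Peptide.Cterm = rep_len(cterm, n),
             Ratio.M.L.rep1 = ratio_5,
             Ratio.H.L.rep1 = ratio_15,
             stringsAsFactors = FALSE)
}

# Background model by literal re-implementation: per-protein median of
# log2 ratios, ascending sort (ties by id), lowest floor(f*n) = background;
# median over all quantified, sample SD over the background set.
oracle_background <- function(df, channel, f = 0.9) {
  prefix <- if (channel == "ML") "Ratio.M.L.rep" else "Ratio.H.L.rep"
  cols <- grep(prefix, names(df), fixed = TRUE, value = TRUE)
  med <- numeric(0)
  ids <- character(0)
  for (i in seq_len(nrow(df))) {
    vals <- log2(as.numeric(df[i, cols]))
    vals <- vals[!is.na(vals)]
    if (length(vals)) {
      med <- c(med, median(vals))
      ids <- c(ids, df$Protein.ID[i])
    }
  }
  ord <- order(med, ids)
  bg <- med[ord][seq_len(floor(f * length(med)))]
  list(median_all = median(med), median_bg = median(bg), sd_bg = sd(bg),
       n_background = length(bg), n_quantified = length(med))
}

# Exhaustive interactor-calling oracle: tests every (protein, channel)
# against both criteria with explicit loops.
oracle_calls <- function(df, cutoff_ml, cutoff_hl, min_rep = 2, fold = 2) {
  out <- data.frame(Protein.ID = df$Protein.ID, enr5 = FALSE, enr15 = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    for (ch in c("ML", "HL")) {
      prefix <- if (ch == "ML") "Ratio.M.L.rep" else "Ratio.H.L.rep"
      cols <- grep(prefix, names(df), fixed = TRUE, value = TRUE)
      vals <- as.numeric(df[i, cols])
      vals <- vals[!is.na(vals)]
      crit1 <- sum(vals >= fold) >= min_rep
      cutoff <- if (ch == "ML") cutoff_ml else cutoff_hl
      crit2 <- length(vals) > 0 && median(log2(vals)) > cutoff
      if (crit1 && crit2) {
        if (ch == "ML") out$enr5[i] <- TRUE else out$enr15[i] <- TRUE
      }
    }
  }
  out$called <- out$enr5 | out$enr15
  out
}

# Exact rank-sum enumeration: all C(n+m, n) assignments of the pooled
# values to group A; two-sided p = 2 * min(tail probs), capped at 1.
oracle_ranksum <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n <- length(a)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx)
    sum(ranks[idx]) - n * (n + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# Upper-tail hypergeometric by direct combinatorial summation.
oracle_hyper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

fixture <- function(name) {
  path <- system.file("extdata", name, package = "silacsig")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}
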