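#' Configuration for simulating an AP-MS interactome experiment
#'
#' Describes a triple-SILAC pull-down design: light = unstimulated
#' control, medium = 5 min and heavy = 15 min of receptor stimulation,
#' with `n_replicates` replicate experiments. A background-binder majority
#' has latent log2 ratios centred at 0 with spread `sigma_background`; a
#' `frac_interactors` minority of true interactors is shifted by the
#' configured per-channel effects. Each replicate measurement adds
#' independent Gaussian noise `sigma_replicate`, and each
#' (protein, replicate, channel) cell is missing independently with
#' probability `dropout_prob` (missing values are encoded explicitly,
#' never as zero). All randomness flows from the single `seed`.
#'
#' @param n_proteins Number of protein groups.
#' @param frac_interactors Fraction of proteins that are true interactors.
#' @param effect_log2_5min,effect_log2_15min Mean log2 enrichment of true
#'   interactors in the M/L (5 min) and H/L (15 min) channels.
#' @param sigma_background SD of the protein-level background log2 ratios.
#' @param sigma_replicate SD of per-replicate measurement noise (log2).
#' @param n_replicates Number of replicate experiments.
#' @param dropout_prob Probability that a single ratio cell is missing.
#' @param seed Integer seed; identical configs give identical output.
#' @return An object of class `interactome_sim_config`.
#' @export
interactome_sim_config <- function(n_proteins = 3000,
                                   frac_interactors = 0.05,
                                   effect_log2_5min = 2.0,
                                   effect_log2_15min = 2.0,
                                   sigma_background = 0.5,
                                   sigma_replicate = 0.25,
                                   n_replicates = 4,
                                   dropout_prob = 0.1,
                                   seed = 1) {
  n_proteins <- .check_count(n_proteins, "n_proteins", min = 1L)
  .check_proportion(frac_interactors, "frac_interactors")
  .check_nonneg(sigma_background, "sigma_background")
  .check_nonneg(sigma_replicate, "sigma_replicate")
  n_replicates <- .check_count(n_replicates, "n_replicates", min = 1L)
  .check_proportion(dropout_prob, "dropout_prob")
  seed <- .check_count(seed, "seed", min = 0L)
  structure(list(n_proteins = n_proteins,
                 frac_interactors = frac_interactors,
                 effect_log2_5min = effect_log2_5min,
                 effect_log2_15min = effect_log2_15min,
                 sigma_background = sigma_background,
                 sigma_replicate = sigma_replicate,
                 n_replicates = n_replicates,
                 dropout_prob = dropout_prob,
                 seed = seed),
            class = "interactome_sim_config")
}

#' Simulate replicate protein-group tables with ground truth
#'
#' Generates a `protein_groups` table in the package's TSV dialect (one
#' ratio-column pair per replicate) together with a ground-truth table.
#' Interactor labels and latent protein-level ratios are drawn before
#' measurement noise and dropout are applied.
#'
#' @param config An [interactome_sim_config()].
#' @return A list with `table` (a `protein_groups` data.frame) and `truth`
#'   (one row per protein: `Protein.ID`, `truth_is_interactor`,
#'   `truth_latent_log2_ml`, `truth_latent_log2_hl`).
#' @export
simulate_interactome <- function(config) {
  stopifnot(inherits(config, "interactome_sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  n_int <- round(config$frac_interactors * n)
  is_int <- seq_len(n) <= n_int
  ids <- sprintf("PROT%05d", seq_len(n))

  latent <- function(effect) {
    stats::rnorm(n, mean = ifelse(is_int, effect, 0),
                 sd = config$sigma_background)
  }
  lat_ml <- latent(config$effect_log2_5min)
  lat_hl <- latent(config$effect_log2_15min)

  reps <- function(lat) {
    m <- matrix(lat, n, config$n_replicates) +
      matrix(stats::rnorm(n * config$n_replicates, 0,
                          config$sigma_replicate), n, config$n_replicates)
    if (config$dropout_prob > 0)
      m[matrix(stats::runif(n * config$n_replicates) < config$dropout_prob,
               n, config$n_replicates)] <- NA_real_
    2^m
  }
  m_ml <- reps(lat_ml)
  m_hl <- reps(lat_hl)

  tab <- data.frame(Protein.ID = ids,
                    Gene.name = sprintf("GENE%05d", seq_len(n)),
                    stringsAsFactors = FALSE)
  for (k in seq_len(config$n_replicates)) {
    tab[[sprintf("Ratio.M.L.rep%d", k)]] <- m_ml[, k]
    tab[[sprintf("Ratio.H.L.rep%d", k)]] <- m_hl[, k]
  }
  truth <- data.frame(Protein.ID = ids,
                      truth_is_interactor = is_int,
                      truth_latent_log2_ml = lat_ml,
                      truth_latent_log2_hl = lat_hl,
                      stringsAsFactors = FALSE)
  list(table = validate_protein_groups(tab), truth = truth)
}

#' Simulate a dataset with no true interactors
#'
#' Convenience wrapper around [simulate_interactome()] with
#' `frac_interactors = 0`; used for false-positive-rate calibration.
#'
#' @param config An [interactome_sim_config()]; its `frac_interactors` is
#'   overridden to 0.
#' @return As [simulate_interactome()]; the truth table is all-negative.
#' @export
simulate_null_dataset <- function(config) {
  stopifnot(inherits(config, "interactome_sim_config"))
  config$frac_interactors <- 0
  simulate_interactome(config)
}

# Dynamics classes the PTM generator can spike in, with default mean
# log2 effects (5 min, 15 min). The early-transient default mirrors an
# IkB-alpha-like profile: 19.5-fold at 5 min decaying to 2-fold at 15 min.
.default_class_effects <- function() {
  list("early-transient" = c(log2(19.5), 1.0),
       "sustained" = c(1.8, 1.8),
       "late" = c(0, 1.8),
       "down-regulated" = c(-2, -2))
}

#' Configuration for simulating PTM-site tables
#'
#' Describes the generation of a phosphorylation-site table and a di-Gly
#' (ubiquitylation) site table sharing one protein pool, so the layers
#' overlap at the protein level. A fraction of sites is regulated; each
#' regulated site gets a temporal dynamics class drawn from
#' `dynamics_mix` (Ser/Thr and di-Gly sites) or `tyr_dynamics_mix`
#' (tyrosine sites, which in receptor signaling are predominantly
#' early-transient with large fold changes). Site-level latent log2 ratios
#' are the class mean effects plus `N(0, sigma_effect)`; replicates add
#' `N(0, sigma_replicate)` noise with dropout. Quality scores are drawn so
#' that configurable fractions of sites fail each confidence filter, and
#' a configurable fraction of di-Gly sites is placed at the peptide
#' C-terminus to exercise the internal-lysine rule.
#'
#' @param n_phospho,n_digly Numbers of phosphorylation and di-Gly sites.
#' @param frac_tyr Fraction of phospho sites on tyrosine (default 0.041;
#'   the remainder is split between Ser and Thr at 86:14).
#' @param frac_regulated_phospho,frac_regulated_digly Fractions of
#'   regulated sites per modification.
#' @param dynamics_mix,tyr_dynamics_mix Named probability vectors over the
#'   dynamics classes in `class_effects`; must sum to 1.
#' @param class_effects Named list of mean log2 effect pairs
#'   (5 min, 15 min) per dynamics class.
#' @param sigma_effect SD of site-level effect spread (log2).
#' @param sigma_replicate SD of replicate noise (log2).
#' @param n_replicates Number of replicate experiments (default 2).
#' @param dropout_prob Probability a single ratio cell is missing.
#' @param frac_fail_localization,frac_fail_score,frac_fail_pep Fractions of
#'   sites failing each confidence filter.
#' @param frac_cterminal_digly Fraction of di-Gly sites at the peptide
#'   C-terminus. Default 0.05.
#' @param n_protein_pool Size of the shared protein pool.
#' @param seed Integer seed.
#' @return An object of class `ptm_sim_config`.
#' @export
ptm_sim_config <- function(n_phospho = 10000,
                           n_digly = 6000,
                           frac_tyr = 0.041,
                           frac_regulated_phospho = 0.20,
                           frac_regulated_digly = 0.06,
                           dynamics_mix = c("early-transient" = 0.20,
                                            "sustained" = 0.55,
                                            "late" = 0.10,
                                            "down-regulated" = 0.15),
                           tyr_dynamics_mix = c("early-transient" = 0.70,
                                                "sustained" = 0.15,
                                                "late" = 0.05,
                                                "down-regulated" = 0.10),
                           class_effects = .default_class_effects(),
                           sigma_effect = 0.3,
                           sigma_replicate = 0.25,
                           n_replicates = 2,
                           dropout_prob = 0.05,
                           frac_fail_localization = 0.10,
                           frac_fail_score = 0.05,
                           frac_fail_pep = 0.05,
                           frac_cterminal_digly = 0.05,
                           n_protein_pool = 2500,
                           seed = 1) {
  n_phospho <- .check_count(n_phospho, "n_phospho", min = 1L)
  n_digly <- .check_count(n_digly, "n_digly", min = 1L)
  .check_proportion(frac_tyr, "frac_tyr")
  .check_proportion(frac_regulated_phospho, "frac_regulated_phospho")
  .check_proportion(frac_regulated_digly, "frac_regulated_digly")
  for (nm in c("dynamics_mix", "tyr_dynamics_mix")) {
    mix <- get(nm)
    if (is.null(names(mix)) || !all(names(mix) %in% names(class_effects)) ||
        any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
      .stop("silacsig_config_error",
            "'%s' must be a probability distribution over the classes in 'class_effects'",
            nm)
  }
  .check_nonneg(sigma_effect, "sigma_effect")
  .check_nonneg(sigma_replicate, "sigma_replicate")
  n_replicates <- .check_count(n_replicates, "n_replicates", min = 1L)
  .check_proportion(dropout_prob, "dropout_prob")
  .check_proportion(frac_fail_localization, "frac_fail_localization")
  .check_proportion(frac_fail_score, "frac_fail_score")
  .check_proportion(frac_fail_pep, "frac_fail_pep")
  .check_proportion(frac_cterminal_digly, "frac_cterminal_digly")
  n_protein_pool <- .check_count(n_protein_pool, "n_protein_pool", min = 1L)
  seed <- .check_count(seed, "seed", min = 0L)
  structure(list(n_phospho = n_phospho, n_digly = n_digly,
                 frac_tyr = frac_tyr,
                 frac_regulated_phospho = frac_regulated_phospho,
                 frac_regulated_digly = frac_regulated_digly,
                 dynamics_mix = dynamics_mix,
                 tyr_dynamics_mix = tyr_dynamics_mix,
                 class_effects = class_effects,
                 sigma_effect = sigma_effect,
                 sigma_replicate = sigma_replicate,
                 n_replicates = n_replicates,
                 dropout_prob = dropout_prob,
                 frac_fail_localization = frac_fail_localization,
                 frac_fail_score = frac_fail_score,
                 frac_fail_pep = frac_fail_pep,
                 frac_cterminal_digly = frac_cterminal_digly,
                 n_protein_pool = n_protein_pool,
                 seed = seed),
            class = "ptm_sim_config")
}

#' Simulate phosphorylation and di-Gly site tables with ground truth
#'
#' @param config A [ptm_sim_config()].
#' @return A list with `phospho` and `digly` (`ptm_sites` tables) and
#'   `truth` (one row per site, in table order: site key plus
#'   `truth_class` — a dynamics class or `"unregulated"` —
#'   `truth_latent_log2_ml`, `truth_latent_log2_hl`,
#'   `truth_passes_quality`).
#' @export
simulate_ptm_sites <- function(config) {
  stopifnot(inherits(config, "ptm_sim_config"))
  set.seed(config$seed)
  phospho <- .simulate_site_table(config, "phospho")
  digly <- .simulate_site_table(config, "diGly")
  truth <- rbind(phospho$truth, digly$truth)
  row.names(truth) <- NULL
  list(phospho = phospho$table, digly = digly$table, truth = truth)
}

.simulate_site_table <- function(config, modification) {
  n <- if (modification == "phospho") config$n_phospho else config$n_digly
  frac_reg <- if (modification == "phospho") config$frac_regulated_phospho
              else config$frac_regulated_digly

  if (modification == "phospho") {
    residue <- sample(c("S", "T", "Y"), n, replace = TRUE,
                      prob = c(0.86 * (1 - config$frac_tyr),
                               0.14 * (1 - config$frac_tyr),
                               config$frac_tyr))
  } else {
    residue <- rep("K", n)
  }
  protein <- sprintf("PROT%05d",
                     sample.int(config$n_protein_pool, n, replace = TRUE))
  position <- sample.int(1000L, n, replace = TRUE)

  # truth labels drawn before any noise
  regulated <- stats::runif(n) < frac_reg
  classes <- names(config$class_effects)
  truth_class <- rep("unregulated", n)
  for (res_group in c("tyr", "other")) {
    sel <- regulated & (if (res_group == "tyr") residue == "Y"
                        else residue != "Y")
    mix <- if (res_group == "tyr") config$tyr_dynamics_mix
           else config$dynamics_mix
    if (any(sel))
      truth_class[sel] <- sample(names(mix), sum(sel), replace = TRUE,
                                 prob = as.numeric(mix))
  }
  eff <- matrix(0, n, 2)
  for (cl in classes) {
    sel <- truth_class == cl
    if (any(sel)) {
      eff[sel, 1] <- config$class_effects[[cl]][1]
      eff[sel, 2] <- config$class_effects[[cl]][2]
    }
  }
  lat_ml <- eff[, 1] + stats::rnorm(n, 0, config$sigma_effect) *
    (truth_class != "unregulated")
  lat_hl <- eff[, 2] + stats::rnorm(n, 0, config$sigma_effect) *
    (truth_class != "unregulated")

  reps <- function(lat) {
    m <- matrix(lat, n, config$n_replicates) +
      matrix(stats::rnorm(n * config$n_replicates, 0,
                          config$sigma_replicate), n, config$n_replicates)
    if (config$dropout_prob > 0)
      m[matrix(stats::runif(n * config$n_replicates) < config$dropout_prob,
               n, config$n_replicates)] <- NA_real_
    2^m
  }
  m_ml <- reps(lat_ml)
  m_hl <- reps(lat_hl)

  fail_loc <- stats::runif(n) < config$frac_fail_localization
  fail_score <- stats::runif(n) < config$frac_fail_score
  fail_pep <- stats::runif(n) < config$frac_fail_pep
  loc <- ifelse(fail_loc, stats::runif(n, 0, 0.75),
                stats::runif(n, 0.75, 1))
  score <- ifelse(fail_score, stats::runif(n, 0, 40),
                  stats::runif(n, 40, 180))
  pep <- ifelse(fail_pep, stats::runif(n, 0.01, 0.5),
                stats::runif(n, 0, 0.01))
  cterm <- if (modification == "diGly")
    stats::runif(n) < config$frac_cterminal_digly else rep(FALSE, n)
  passes <- !fail_loc & !fail_score & !fail_pep & !cterm

  tab <- data.frame(Protein.ID = protein,
                    Residue = residue,
                    Position = position,
                    Modification = modification,
                    Localization.prob = loc,
                    Score = score,
                    PEP = pep,
                    Peptide.Cterm = cterm,
                    stringsAsFactors = FALSE)
  for (k in seq_len(config$n_replicates)) {
    tab[[sprintf("Ratio.M.L.rep%d", k)]] <- m_ml[, k]
    tab[[sprintf("Ratio.H.L.rep%d", k)]] <- m_hl[, k]
  }
  truth <- data.frame(Protein.ID = protein,
                      Position = position,
                      Residue = residue,
                      Modification = modification,
                      truth_class = truth_class,
                      truth_latent_log2_ml = lat_ml,
                      truth_latent_log2_hl = lat_hl,
                      truth_passes_quality = passes,
                      stringsAsFactors = FALSE)
  list(table = validate_ptm_sites(tab, modification), truth = truth)
}

#' Write a ground-truth table
#'
#' @param truth A truth data.frame from a simulator.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) .write_tsv(truth, path)
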