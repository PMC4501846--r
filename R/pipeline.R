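#' Configuration for the full analysis pipeline
#'
#' Bundles the inputs (tables, file paths, or simulator configurations)
#' and every tunable parameter of the analysis. All defaults are the
#' standard values of the method: 90% background fraction, median + 2SD
#' cutoffs, >= 2-fold in >= 2 replicates, site confidence filters
#' 0.75/40/0.01, regulation thresholds 2 and 0.5.
#'
#' @param protein_groups,phospho_sites,digly_sites Inputs per layer: a
#'   file path, an in-memory table, or `NULL`. A layer that is `NULL` and
#'   has no simulator configuration is skipped.
#' @param interactome_sim,ptm_sim Optional [interactome_sim_config()] /
#'   [ptm_sim_config()]; when supplied the corresponding tables are
#'   simulated instead of read.
#' @param quality A [quality_thresholds()] object.
#' @param apply_quality_to_digly Whether the score/PEP/localization
#'   filters also apply to di-Gly sites (default TRUE).
#' @param regulation A [regulation_thresholds()] object.
#' @param background_fraction,sd_multiplier,min_replicates,fold_threshold
#'   Interactor-calling parameters (see [fit_background_model()] and
#'   [call_interactors()]).
#' @param transient_drop See [assign_dynamics_class()].
#' @param output_dir Directory for the calls TSVs, edge list and report
#'   JSON; `NULL` keeps everything in memory.
#' @param seed Integer seed echoed into the report.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(protein_groups = NULL,
                            phospho_sites = NULL,
                            digly_sites = NULL,
                            interactome_sim = NULL,
                            ptm_sim = NULL,
                            quality = quality_thresholds(),
                            apply_quality_to_digly = TRUE,
                            regulation = regulation_thresholds(),
                            background_fraction = 0.90,
                            sd_multiplier = 2,
                            min_replicates = 2,
                            fold_threshold = 2.0,
                            transient_drop = 2.0,
                            output_dir = NULL,
                            seed = 1) {
  stopifnot(inherits(quality, "quality_thresholds"),
            inherits(regulation, "regulation_thresholds"))
  .check_proportion(background_fraction, "background_fraction")
  if (!is.numeric(sd_multiplier) || sd_multiplier <= 0)
    .stop("silacsig_config_error", "'sd_multiplier' must be positive")
  structure(list(protein_groups = protein_groups,
                 phospho_sites = phospho_sites,
                 digly_sites = digly_sites,
                 interactome_sim = interactome_sim,
                 ptm_sim = ptm_sim,
                 quality = quality,
                 apply_quality_to_digly = apply_quality_to_digly,
                 regulation = regulation,
                 background_fraction = background_fraction,
                 sd_multiplier = sd_multiplier,
                 min_replicates = .check_count(min_replicates,
                                               "min_replicates"),
                 fold_threshold = fold_threshold,
                 transient_drop = transient_drop,
                 output_dir = output_dir,
                 seed = .check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stop("silacsig_stage_error", "stage '%s': %s", name,
          conditionMessage(e))
  })
}

#' Run the full signalosome / PTM analysis pipeline
#'
#' Executes, for whichever layers are configured: interactor calling
#' (background model, cutoffs, two-criteria calls, Venn partition), PTM
#' confidence filtering and regulation calling with dynamics classes,
#' residue-class statistics, and protein-level integration. When
#' `output_dir` is set, all call tables, the edge list and the summary
#' report (JSON, written last) are saved; the run is deterministic given
#' the configuration, and every reported count can be re-derived from the
#' emitted call TSVs.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `silacsig_report`: a nested list with the
#'   per-layer count tables, background models and cutoffs, Venn
#'   partition, software version and configuration echo, plus the
#'   intermediate results (`calls`) as attributes for programmatic use.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- list(
    software = list(package = "silacsig",
                    version = as.character(utils::packageVersion("silacsig"))),
    config = list(background_fraction = config$background_fraction,
                  sd_multiplier = config$sd_multiplier,
                  min_replicates = config$min_replicates,
                  fold_threshold = config$fold_threshold,
                  transient_drop = config$transient_drop,
                  up_fold = config$regulation$up_fold,
                  down_fold = config$regulation$down_fold,
                  min_localization_prob = config$quality$min_localization_prob,
                  min_score = config$quality$min_score,
                  max_pep = config$quality$max_pep,
                  apply_quality_to_digly = config$apply_quality_to_digly,
                  seed = config$seed)
  )
  out <- list()

  proteins <- .stage("load-interactome", .load_table(
    config$protein_groups, config$interactome_sim, "protein_groups"))
  if (!is.null(proteins)) {
    res <- .stage("interactome", {
      bg_ml <- fit_background_model(proteins, "ML",
                                    config$background_fraction)
      bg_hl <- fit_background_model(proteins, "HL",
                                    config$background_fraction)
      cutoffs <- derive_cutoffs(bg_ml, bg_hl, config$sd_multiplier)
      calls <- call_interactors(proteins, cutoffs,
                                config$min_replicates,
                                config$fold_threshold)
      list(bg_ml = bg_ml, bg_hl = bg_hl, cutoffs = cutoffs, calls = calls)
    })
    venn <- partition_venn(res$calls)
    report$interactome <- list(
      n_quantified = nrow(res$calls),
      background_ml = .echo_background(res$bg_ml),
      background_hl = .echo_background(res$bg_hl),
      cutoff_log2_ml = res$cutoffs$cutoff_log2_ml,
      cutoff_log2_hl = res$cutoffs$cutoff_log2_hl,
      n_interactors = sum(res$calls$interactor),
      venn = list(n_both = venn$n_both, n_only_5min = venn$n_only_t1,
                  n_only_15min = venn$n_only_t2, n_total = venn$n_total))
    out$interactome <- res
  }

  for (layer in c("phospho", "digly")) {
    input <- if (layer == "phospho") config$phospho_sites else
      config$digly_sites
    sites <- .stage(paste0("load-", layer),
                    .load_table(input, config$ptm_sim, layer))
    if (is.null(sites)) next
    modification <- if (layer == "phospho") "phospho" else "diGly"
    res <- .stage(layer, {
      sites <- validate_ptm_sites(as.data.frame(sites), modification)
      n_input <- nrow(sites)
      n_cterm_removed <- 0L
      if (modification == "diGly") {
        internal <- require_internal_digly(sites)
        n_cterm_removed <- nrow(internal$rejected)
        sites <- internal$kept
      }
      if (modification == "phospho" || config$apply_quality_to_digly) {
        conf <- filter_confident_sites(sites, config$quality)
        sites <- conf$kept
      }
      calls <- classify_regulation(sites, config$regulation,
                                   config$transient_drop)
      list(n_input = n_input, n_cterm_removed = n_cterm_removed,
           sites = sites, calls = calls)
    })
    counts <- .regulation_counts(res$calls)
    block <- c(list(n_input = res$n_input,
                    n_confident = nrow(res$calls)), counts)
    if (modification == "diGly")
      block$n_peptide_cterm_removed <- res$n_cterm_removed
    if (modification == "phospho") {
      rcs <- residue_class_summary(res$calls)
      block$residue_class <- lapply(seq_len(nrow(rcs)), function(i)
        as.list(rcs[i, , drop = FALSE]))
    }
    report[[layer]] <- block
    out[[layer]] <- res
  }

  if (!is.null(out$phospho) && !is.null(out$digly)) {
    coreg <- .stage("integration", co_regulated_proteins(
      out$phospho$calls, out$digly$calls,
      if (!is.null(out$interactome)) out$interactome$calls else NULL))
    report$integration <- list(
      n_proteins_with_up_site = nrow(coreg),
      n_co_regulated = sum(coreg$co_regulated),
      n_in_signalosome = sum(coreg$in_signalosome))
    out$integration <- coreg
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    if (!is.null(out$interactome)) {
      write_calls(out$interactome$calls, p("interactor_calls.tsv"))
      export_edge_list(out$interactome$calls, p("interactome_edges.tsv"))
    }
    if (!is.null(out$phospho))
      write_calls(out$phospho$calls, p("phospho_calls.tsv"))
    if (!is.null(out$digly))
      write_calls(out$digly$calls, p("digly_calls.tsv"))
    if (!is.null(out$integration))
      write_calls(out$integration, p("coregulation.tsv"))
    write_summary(report, p("report.json"))   # report written last
  }

  structure(report, class = "silacsig_report", results = out)
}

.echo_background <- function(bg) {
  list(median_log2 = bg$median_log2,
       background_median_log2 = bg$background_median_log2,
       sd_log2 = bg$sd_log2,
       n_background = bg$n_background,
       n_quantified = bg$n_quantified)
}

.regulation_counts <- function(calls) {
  list(t5min = list(n_quantified = sum(!is.na(calls$ratio_5min)),
                    n_up = sum(calls$class_5min == "up"),
                    n_down = sum(calls$class_5min == "down")),
       t15min = list(n_quantified = sum(!is.na(calls$ratio_15min)),
                     n_up = sum(calls$class_15min == "up"),
                     n_down = sum(calls$class_15min == "down")))
}

.load_table <- function(input, sim_config, what) {
  if (!is.null(input)) {
    if (is.character(input)) {
      return(switch(what,
                    protein_groups = read_protein_groups(input),
                    phospho = read_ptm_sites(input, "phospho"),
                    digly = read_ptm_sites(input, "diGly")))
    }
    return(input)
  }
  if (is.null(sim_config)) return(NULL)
  if (what == "protein_groups") return(simulate_interactome(sim_config)$table)
  sim <- simulate_ptm_sites(sim_config)
  if (what == "phospho") sim$phospho else sim$digly
}

#' @export
print.silacsig_report <- function(x, ...) {
  cat("silacsig pipeline report\n")
  if (!is.null(x$interactome))
    cat(sprintf(
      "  interactome : %d proteins, %d interactors (both %d / 5min %d / 15min %d)\n",
      x$interactome$n_quantified, x$interactome$n_interactors,
      x$interactome$venn$n_both, x$interactome$venn$n_only_5min,
      x$interactome$venn$n_only_15min))
  for (layer in c("phospho", "digly")) {
    b <- x[[layer]]
    if (is.null(b)) next
    cat(sprintf(
      "  %-11s : %d sites in, %d confident | 5 min: %d up / %d down | 15 min: %d up / %d down\n",
      layer, b$n_input, b$n_confident, b$t5min$n_up, b$t5min$n_down,
      b$t15min$n_up, b$t15min$n_down))
  }
  if (!is.null(x$integration))
    cat(sprintf("  integration : %d proteins with up-regulated sites, %d co-regulated\n",
                x$integration$n_proteins_with_up_site,
                x$integration$n_co_regulated))
  invisible(x)
}
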