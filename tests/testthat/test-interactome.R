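test_that("background model matches a brute-force oracle on the toy table", {
  pg <- read_protein_groups(fixture("toy_protein_groups.tsv"))
  for (ch in c("ML", "HL")) {
    model <- fit_background_model(pg, ch)
    oracle <- oracle_background(pg, ch)
    expect_equal(model$median_log2, oracle$median_all)
    expect_equal(model$background_median_log2, oracle$median_bg)
    expect_equal(model$sd_log2, oracle$sd_bg)
    expect_equal(model$n_background, oracle$n_background)  # floor(0.9 * 10)
    expect_equal(model$n_quantified, oracle$n_quantified)
  }
})

test_that("a flat table gives a degenerate null model", {
  flat <- make_pg(matrix(0, 5, 2), matrix(0, 5, 2))
  model <- fit_background_model(flat, "ML")
  expect_equal(model$median_log2, 0)
  expect_equal(model$sd_log2, 0)
  expect_equal(derive_cutoffs(model, model)$cutoff_log2_ml, 0)
})

test_that("too few quantified proteins raise insufficient-data errors", {
  tiny <- make_pg(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_error(fit_background_model(tiny, "ML"), "at least 3",
               class = "silacsig_insufficient_data")
  sparse <- make_pg(rbind(c(0, 0), c(NA, NA), c(0, 0), c(0, 0)),
                    matrix(0, 4, 2))
  # 3 quantified -> background floor(2.7) = 2, allowed
  expect_equal(fit_background_model(sparse, "ML")$n_background, 2)
})

test_that("cutoffs follow median + k * SD and grow with the SD", {
  mk <- function(med, sd) structure(
    list(channel = "ML", median_log2 = med, sd_log2 = sd),
    class = "silac_background")
  expect_equal(derive_cutoffs(mk(0.20, 0.58), mk(0, 0))$cutoff_log2_ml, 1.36)
  set.seed(1)
  for (i in 1:25) {
    med <- runif(1, -1, 1)
    sds <- sort(runif(2, 0, 2))
    cuts <- vapply(sds, function(s)
      derive_cutoffs(mk(med, s), mk(0, 0))$cutoff_log2_ml, numeric(1))
    expect_lt(cuts[1], cuts[2])
  }
})

test_that("a ratio of exactly 2 in 2 of 4 replicates passes criterion (i)", {
  ml <- rbind(log2(c(2.0, 2.0, 1.2, 1.0)))
  hl <- rbind(log2(c(1.0, 1.1, 1.0, 0.9)))
  pg <- make_pg(ml, hl)
  calls <- call_interactors(pg, cutoff_set(0.1, 0.1))
  expect_true(calls$enriched_5min)    # boundary inclusive
  expect_false(calls$enriched_15min)
  expect_true(calls$interactor)
  # one supporting replicate is not enough
  calls2 <- call_interactors(make_pg(rbind(log2(c(2.5, 1.0, 1.0, 1.0))), hl),
                             cutoff_set(0.0, 0.1))
  expect_false(calls2$interactor)
})

test_that("six-protein toy spanning the rule combinations matches the oracle", {
  # rows: pass both; pass (i) only; pass (ii) only; pass in HL only;
  #       under-quantified; background
  ml <- rbind(log2(c(3, 3, 2.5, 3)),
              log2(c(2, 2, 0.3, 0.25)),
              log2(c(3, 1.9, 1.9, 1.9)),
              log2(c(1, 1, 1, 1)),
              c(log2(3), NA, NA, NA),
              log2(c(1, 1.1, 0.9, 1)))
  hl <- rbind(log2(c(1, 1, 1, 1)),
              log2(c(1, 1, 1, 1)),
              log2(c(1, 1, 1, 1)),
              log2(c(4, 4, 3.5, 4)),
              c(NA, NA, NA, log2(3)),
              log2(c(1, 0.9, 1.1, 1)))
  pg <- make_pg(ml, hl)
  calls <- call_interactors(pg, cutoff_set(1.0, 1.0))
  oracle <- oracle_calls(pg, 1.0, 1.0)
  expect_equal(calls$enriched_5min, oracle$enr5)
  expect_equal(calls$enriched_15min, oracle$enr15)
  expect_equal(calls$interactor, oracle$called)
  expect_equal(calls$interactor, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
})

test_that("empty record lists give empty call lists", {
  empty <- data.frame(Protein.ID = character(0),
                      Ratio.M.L.rep1 = numeric(0),
                      Ratio.H.L.rep1 = numeric(0))
  expect_equal(nrow(call_interactors(empty, cutoff_set(1, 1))), 0)
})

test_that("min_replicates beyond the table raises a configuration error", {
  pg <- make_pg(matrix(0, 4, 2), matrix(0, 4, 2))
  expect_error(call_interactors(pg, cutoff_set(1, 1), min_replicates = 3),
               "min_replicates", class = "silacsig_config_error")
})

test_that("scale equivariance: rescaling a channel shifts cutoff and medians equally", {
  sim <- simulate_interactome(interactome_sim_config(n_proteins = 200,
                                                     seed = 17))
  pg <- sim$table
  scaled <- pg
  ml_cols <- grep("Ratio.M.L", names(pg), value = TRUE)
  for (col in ml_cols) scaled[[col]] <- scaled[[col]] * 8   # +3 in log2
  m1 <- fit_background_model(pg, "ML")
  m2 <- fit_background_model(scaled, "ML")
  expect_equal(m2$median_log2, m1$median_log2 + 3, tolerance = 1e-10)
  expect_equal(m2$sd_log2, m1$sd_log2, tolerance = 1e-10)
  hl <- fit_background_model(pg, "HL")
  pass1 <- call_interactors(pg, derive_cutoffs(m1, hl),
                            fold_threshold = 1e-9)
  pass2 <- call_interactors(scaled, derive_cutoffs(m2, hl),
                            fold_threshold = 1e-9)
  # with criterion (i) neutralised, the criterion-(ii) set is unchanged
  expect_equal(pass1$enriched_5min, pass2$enriched_5min)
})

test_that("venn partition equals direct set arithmetic on random flag pairs", {
  set.seed(99)
  for (i in 1:5) {
    calls <- data.frame(enriched_5min = runif(20) < 0.4,
                        enriched_15min = runif(20) < 0.4)
    v <- partition_venn(calls)
    expect_equal(v$n_both, sum(calls$enriched_5min & calls$enriched_15min))
    expect_equal(v$n_only_t1, sum(calls$enriched_5min & !calls$enriched_15min))
    expect_equal(v$n_only_t2, sum(!calls$enriched_5min & calls$enriched_15min))
    expect_equal(v$n_total, v$n_both + v$n_only_t1 + v$n_only_t2)
  }
  none <- partition_venn(data.frame(enriched_5min = logical(0),
                                    enriched_15min = logical(0)))
  expect_equal(unlist(none), c(n_both = 0, n_only_t1 = 0, n_only_t2 = 0,
                               n_total = 0))
})

test_that("recovery is monotone in effect size and fold threshold", {
  sens_at <- function(effect) {
    cfg <- interactome_sim_config(n_proteins = 600, frac_interactors = 0.05,
                                  effect_log2_5min = effect,
                                  effect_log2_15min = effect, seed = 31)
    sim <- simulate_interactome(cfg)
    cut <- derive_cutoffs(fit_background_model(sim$table, "ML"),
                          fit_background_model(sim$table, "HL"))
    calls <- call_interactors(sim$table, cut)
    mean(calls$interactor[sim$truth$truth_is_interactor])
  }
  sens <- vapply(c(0.5, 1.5, 3.0), sens_at, numeric(1))
  expect_true(all(diff(sens) >= 0))

  fdr_at <- function(fold) {
    cfg <- interactome_sim_config(n_proteins = 600, seed = 32)
    sim <- simulate_interactome(cfg)
    cut <- derive_cutoffs(fit_background_model(sim$table, "ML"),
                          fit_background_model(sim$table, "HL"))
    calls <- call_interactors(sim$table, cut, fold_threshold = fold)
    called <- calls$interactor
    if (!any(called)) return(0)
    mean(!sim$truth$truth_is_interactor[called])
  }
  fdr <- vapply(c(1.5, 2.0, 3.0), fdr_at, numeric(1))
  expect_true(all(diff(fdr) <= 1e-12))
})
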