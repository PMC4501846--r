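test_that("regulation classes use inclusive 2-fold / 0.5-fold boundaries", {
  sites <- validate_ptm_sites(
    make_sites(c(2.0, 0.5, 1.0, 1.99), c(1.0, 1.0, 1.0, 0.51)), "phospho")
  calls <- classify_regulation(sites)
  expect_equal(calls$class_5min, c("up", "down", "unchanged", "unchanged"))
  expect_equal(calls$class_15min, rep("unchanged", 4))
})

test_that("per-site ratios are medians over replicates and NA when absent", {
  sites <- make_sites(c(2, 4), c(1, 1))
  sites$Ratio.M.L.rep2 <- c(8, NA)
  sites$Ratio.H.L.rep2 <- c(NA, NA)
  sites$Ratio.H.L.rep1 <- c(NA, 1)
  calls <- classify_regulation(validate_ptm_sites(sites, "phospho"))
  expect_equal(calls$ratio_5min, c(4, 4))   # median(2, 8) = 4
  expect_true(is.na(calls$ratio_15min[1]))
  expect_equal(calls$class_15min, c("missing", "unchanged"))
})

test_that("classification partition is exhaustive and ratio inversion swaps up/down", {
  sim <- simulate_ptm_sites(ptm_sim_config(n_phospho = 800, n_digly = 400,
                                           seed = 23))
  calls <- classify_regulation(sim$phospho)
  expect_true(all(calls$class_5min %in%
                    c("up", "down", "unchanged", "missing")))
  expect_equal(sum(is.na(calls$ratio_5min)),
               sum(calls$class_5min == "missing"))

  inverted <- as.data.frame(sim$phospho)
  for (col in grep("Ratio", names(inverted), value = TRUE))
    inverted[[col]] <- 1 / inverted[[col]]
  inv_calls <- classify_regulation(validate_ptm_sites(inverted, "phospho"))
  expect_equal(sum(inv_calls$class_5min == "up"),
               sum(calls$class_5min == "down"))
  expect_equal(sum(inv_calls$class_5min == "down"),
               sum(calls$class_5min == "up"))
  expect_equal(sum(inv_calls$class_15min == "up"),
               sum(calls$class_15min == "down"))
})

test_that("dynamics rules reproduce the worked temporal profiles", {
  # IkB-alpha-like: 19.5-fold at 5 min decaying to 2-fold at 15 min
  expect_equal(assign_dynamics_class("up", "up", 19.5, 2.0),
               "early-transient")
  # RAB7A-S72-like: > 20-fold sustained at both time points
  expect_equal(assign_dynamics_class("up", "up", 20.5, 22), "sustained")
  expect_equal(assign_dynamics_class("unchanged", "unchanged", 1, 1),
               "unregulated")
  expect_equal(assign_dynamics_class("unchanged", "up", 1.2, 4), "late")
  expect_equal(assign_dynamics_class("down", "unchanged", 0.3, 1.1),
               "down-regulated")
  expect_equal(assign_dynamics_class("down", "up", 0.3, 4), "mixed")
  # up at 5 min only, regardless of drop magnitude
  expect_equal(assign_dynamics_class("up", "unchanged", 2.4, 1.5),
               "early-transient")
})

test_that("dynamics classifier recovers simulated class labels", {
  cfg <- ptm_sim_config(n_phospho = 2000, n_digly = 100,
                        frac_regulated_phospho = 0.5,
                        sigma_effect = 0.2, sigma_replicate = 0.2,
                        dropout_prob = 0, seed = 29)
  sim <- simulate_ptm_sites(cfg)
  calls <- classify_regulation(sim$phospho)
  truth <- sim$truth[sim$truth$Modification == "phospho", ]
  expect_gt(mean(calls$dynamics == truth$truth_class), 0.95)
})

test_that("residue-class summary matches hand arithmetic on a toy table", {
  sites <- validate_ptm_sites(
    make_sites(c(4, 5, 3, 1.5, 1.7), c(1, 1, 1, 1, 1),
               residue = c("Y", "Y", "Y", "S", "T")), "phospho")
  calls <- classify_regulation(sites)
  rcs <- residue_class_summary(calls)
  tyr5 <- rcs[rcs$residue_class == "Tyr" & rcs$timepoint == "5min", ]
  st5 <- rcs[rcs$residue_class == "Ser/Thr" & rcs$timepoint == "5min", ]
  expect_equal(tyr5$mean_fold, 4.0)   # mean(4, 5, 3)
  expect_equal(st5$mean_fold, 1.6)    # mean(1.5, 1.7)
  expect_equal(tyr5$n_up, 3)
  expect_equal(st5$n_up, 0)
  expect_equal(tyr5$n_sites + st5$n_sites, 5)
  # single-site class; up-subset variant
  single <- classify_regulation(validate_ptm_sites(
    make_sites(4, 1, residue = "Y"), "phospho"))
  rcs2 <- residue_class_summary(single, subset = "up")
  expect_equal(rcs2$mean_fold[rcs2$residue_class == "Tyr" &
                                rcs2$timepoint == "5min"], 4.0)
  expect_true(is.na(rcs2$mean_fold[rcs2$residue_class == "Ser/Thr" &
                                     rcs2$timepoint == "5min"]))
})

test_that("simulated class means are recovered within sampling error", {
  cfg <- ptm_sim_config(n_phospho = 3000, n_digly = 100,
                        frac_regulated_phospho = 1,
                        dynamics_mix = c("sustained" = 1),
                        tyr_dynamics_mix = c("early-transient" = 1),
                        class_effects = list("early-transient" = c(2, 2),
                                             "sustained" = c(log2(1.6),
                                                             log2(1.6))),
                        sigma_effect = 0.1, sigma_replicate = 0,
                        dropout_prob = 0, seed = 41)
  sim <- simulate_ptm_sites(cfg)
  st <- sim$phospho$Residue != "Y"
  m <- log2(sim$phospho$Ratio.M.L.rep1[st])
  expect_lt(abs(mean(m) - log2(1.6)), 3 * 0.1 / sqrt(sum(st)))
})

test_that("rank-sum test matches exact conventions and handles ties", {
  res <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$p_value, 0.1)   # 2 * (1 / C(6,3))
  expect_equal(res$statistic, 0)

  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$exact)         # ties force the Normal approximation
  expect_equal(same$p_value, 1)

  expect_error(ranksum_test(numeric(0), 1:3),
               class = "silacsig_insufficient_data")

  # one-sided enumeration agrees with the oracle
  a <- c(0.3, 2.2, 1.7, 0.9)
  b <- c(0.1, 0.4, 0.2)
  expect_equal(ranksum_test(a, b, "greater")$p_value,
               oracle_ranksum(a, b, "greater"))
})

test_that("normal approximation stays within 0.05 of exact enumeration", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    vals <- sample(seq_len(40), n + m)   # tie-free
    a <- vals[seq_len(n)]
    b <- vals[-seq_len(n)]
    exact <- ranksum_test(a, b)$p_value
    approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.05)
  }
})

test_that("replicate correlation is Pearson on complete log2 pairs", {
  ml <- cbind(log2(c(1, 2, 4, 8, 16)), log2(c(1, 2, 4, 8, 16)))
  pg <- make_pg(ml, ml)
  expect_equal(replicate_correlation(pg, "ML", 1, 2), 1)

  anti <- make_pg(cbind(ml[, 1], -ml[, 1]), ml)
  expect_equal(replicate_correlation(anti, "ML", 1, 2), -1)

  set.seed(5)
  x <- rnorm(10)
  y <- 0.5 * x + rnorm(10, 0, 0.3)
  pg2 <- make_pg(cbind(x, y), cbind(x, y))
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(replicate_correlation(pg2, "ML", 1, 2), hand)

  few <- make_pg(cbind(c(0, 0, NA, NA), c(0, NA, 0, 0)), matrix(0, 4, 2))
  expect_error(replicate_correlation(few, "ML", 1, 2),
               class = "silacsig_insufficient_data")
})
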