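test_that("independent margins give a latent correlation near zero", {
  marg <- c(0.7, 0.2, 0.1)
  counts <- outer(marg, marg) * 1e4
  fit <- fit_polychoric(pair_table(counts), ci = FALSE)
  expect_lt(abs(fit$rho), 1e-3)
})

test_that("the generating correlation and thresholds are recovered", {
  set.seed(10)
  counts <- draw_bvn_table(1e5, 0.5, c(0, 1))
  fit <- fit_polychoric(pair_table(counts), ci = FALSE)
  expect_equal(fit$rho, 0.5, tolerance = 0.02)
  expect_equal(fit$thresholds$row, c(0, 1), tolerance = 0.02)
  # ML never falls below the likelihood at the generating parameters
  ll_truth <- -twinliab:::.polychoric_nll(counts, 0.5, c(0, 1), c(0, 1))
  expect_gte(fit$loglik, ll_truth - 1e-6)
})

test_that("tetrachoric special case agrees with a brute-force grid search", {
  set.seed(20)
  counts <- draw_bvn_table(5000, 0.45, 0.6)
  fit <- fit_polychoric(pair_table(counts), equal_thresholds = FALSE,
                        ci = FALSE)
  grid <- expand.grid(rho = seq(0.30, 0.60, by = 0.005),
                      t1 = seq(0.4, 0.8, by = 0.005))
  nll <- mapply(function(r, t)
    twinliab:::.polychoric_nll(counts, r, t, t), grid$rho, grid$t1)
  best <- grid[which.min(nll), ]
  expect_equal(fit$rho, best$rho, tolerance = 0.005)
})

test_that("fit is symmetric under transposition with shared thresholds", {
  set.seed(30)
  counts <- draw_bvn_table(3000, 0.4, c(0.2, 1.1))
  f1 <- fit_polychoric(pair_table(counts), ci = FALSE)
  f2 <- fit_polychoric(pair_table(t(counts)), ci = FALSE)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-6)
})

test_that("profile CI brackets the estimate and covers the truth", {
  set.seed(40)
  counts <- draw_bvn_table(2000, 0.5, c(0, 1))
  fit <- fit_polychoric(pair_table(counts))
  expect_lt(fit$rho_ci[1], fit$rho)
  expect_gt(fit$rho_ci[2], fit$rho)
  expect_true(fit$rho_ci[1] < 0.5 && 0.5 < fit$rho_ci[2])
})

test_that("degenerate margins are flagged non-estimable", {
  counts <- matrix(c(50, 30, 0, 0), 2, 2)  # empty second column
  fit <- fit_polychoric(pair_table(counts))
  expect_false(fit$estimable)
  expect_match(fit$reason, "margin")
})

test_that("goodness-of-fit statistic, df accounting and exact-fit limit", {
  set.seed(50)
  counts <- draw_bvn_table(2000, 0.45, c(0.1, 1.2))
  fit <- fit_polychoric(pair_table(counts), ci = FALSE)
  g <- fit$gof
  expect_true(g$estimable)
  # 3x3 with shared thresholds: 8 free cells - 2 thresholds - 1 correlation
  expect_identical(g$df, 5L)
  expect_gte(g$chi2, 0)

  # observed == expected -> chi2 0, p 1
  e <- twinliab:::.bvn_cell_probs(fit$rho, fit$thresholds$row,
                                  fit$thresholds$col) * 1000
  g0 <- multiple_threshold_gof(pair_table(e), fit)
  expect_equal(g0$chi2, 0, tolerance = 1e-6)
  expect_equal(g0$p, 1, tolerance = 1e-6)

  # separate thresholds on a 2x2 saturate the table
  f22 <- fit_polychoric(pair_table(draw_bvn_table(500, 0.3, 0.5)),
                        equal_thresholds = FALSE, ci = FALSE)
  expect_false(f22$gof$estimable)
})

test_that("null calibration: GOF chi2 mean tracks df, rejections ~5%", {
  set.seed(60)
  n_rep <- 400
  chi2 <- numeric(n_rep); pval <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    counts <- draw_bvn_table(643, 0.48, c(1.2249, 2.0433))
    fit <- fit_polychoric(pair_table(counts), ci = FALSE)
    chi2[i] <- fit$gof$chi2
    pval[i] <- fit$gof$p
  }
  ok <- is.finite(chi2)
  # mean chi2 within 3 MC SE of df = 5 (var of chi2_5 is 10)
  expect_lt(abs(mean(chi2[ok]) - 5), 3 * sqrt(10 / sum(ok)))
  rej <- mean(pval[ok] < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / sum(ok)))
})

test_that("grouped reporting covers the standard zygosity groupings", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 3))
  g <- polychoric_groupings(rec, "three",
                            groupings = c("Complete pairs", "MZ", "DZ",
                                          "DZss", "DZos"))
  expect_identical(g$grouping,
                   c("Complete pairs", "MZ", "DZ", "DZss", "DZos"))
  expect_equal(g$n_pairs[g$grouping == "Complete pairs"], 1220)
  expect_true(all(g$gof_p >= 0 & g$gof_p <= 1, na.rm = TRUE))
  # multigroup variant: same groupings, aggregated GOF over member groups
  m <- polychoric_groupings(rec, "three", groupings = "DZss",
                            method = "multigroup")
  expect_true(is.finite(m$gof_p))
  expect_gt(m$gof_df, 5)
})

test_that("MZ exceeds DZ correlations under additive genetics", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 4))
  pc <- polychoric_by_classification(rec, c("two", "three"))
  for (cl in c("two", "three")) {
    sub <- pc[pc$classification == cl, ]
    expect_gt(sub$rho[sub$zygosity == "MZ"], sub$rho[sub$zygosity == "DZ"])
  }
})
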