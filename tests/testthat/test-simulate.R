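test_that("threshold derivation matches independent normal quantiles", {
  thr <- thresholds_from_prevalence(0.0898, 0.0205)
  expect_equal(thr, c(qnorm(1 - 0.1103), qnorm(1 - 0.0205)),
               tolerance = 1e-12)
  expect_equal(thr, c(1.2249, 2.0433), tolerance = 5e-4)
})

test_that("parameter validation enforces the variance decomposition", {
  expect_error(sim_params(a2 = 0.5, c2 = 0.6), "non-negative")
  expect_error(sim_params(a2 = 0.5, c2 = 0.3, e2 = 0.3), "equal 1")
  expect_error(sim_params(a2 = 0.4, c2 = 0.3, d2 = 0.1, e2 = 0.2),
               "both be positive")
  expect_error(sim_params(thresholds = c(1, 1)), "increasing")
  expect_error(sim_params(n_pairs = c("XX-YY" = 10)), "unknown zygosity")
})

test_that("liability-to-status boundary and shift conventions", {
  thr <- c(1.2249, 2.0433)
  expect_identical(liability_to_status(-10, thr), 0L)
  expect_identical(liability_to_status(1.5, thr), 1L)
  expect_identical(liability_to_status(3, thr), 2L)
  # exactly at a threshold -> lower category
  expect_identical(liability_to_status(1.2249, thr), 0L)
  expect_identical(liability_to_status(2.0433, thr), 1L)
  # covariate shift moves the cutpoints, not the liability
  expect_identical(
    liability_to_status(1.5, thr, age = 70, sex = 1, beta_age = 0.05,
                        beta_sex = 0.2, age_ref = 60), 0L)
  expect_error(liability_to_status(0, c(2, 1)), "increasing")
})

test_that("simulation is reproducible and leaves the caller's RNG alone", {
  p <- cohort_preset("aged", seed = 7)
  set.seed(123)
  before <- .Random.seed
  r1 <- simulate_cohort(p)
  expect_identical(before, .Random.seed)
  r2 <- simulate_cohort(p)
  expect_identical(r1, r2)
  r3 <- simulate_cohort(p, seed = 8)
  expect_false(identical(r1$status1, r3$status1))
})

test_that("preset cohorts have the configured structure", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 1))
  expect_identical(nrow(rec), 1220L)
  expect_equal(as.vector(table(rec$zygosity_group)[c(
    "MZ-FF", "MZ-MM", "DZ-FF", "DZ-MM", "DZ-FM", "DZ-MF")]),
    c(491, 152, 263, 73, 136, 105))
  expect_true(all(rec$age >= 50 & rec$age <= 92))
  te <- simulate_cohort(cohort_preset("te", seed = 1))
  expect_identical(nrow(te), 2363L)
})

test_that("perfectly heritable liability makes MZ pairs concordant", {
  p <- sim_params(a2 = 1, e2 = 0,
                  n_pairs = c("MZ-FF" = 300, "DZ-FF" = 300), seed = 3)
  rec <- simulate_cohort(p)
  mz <- rec[rec$zygosity_group == "MZ-FF", ]
  expect_identical(mz$status1, mz$status2)
})

test_that("latent correlations match the ACE algebra at scale", {
  p <- sim_params(a2 = 0.48, e2 = 0.52,
                  n_pairs = c("MZ-FF" = 1e5, "DZ-FF" = 1e5),
                  seed = 11)
  rec <- simulate_cohort(p, keep_liability = TRUE)
  r_mz <- cor(rec$liab1[rec$zygosity_group == "MZ-FF"],
              rec$liab2[rec$zygosity_group == "MZ-FF"])
  r_dz <- cor(rec$liab1[rec$zygosity_group == "DZ-FF"],
              rec$liab2[rec$zygosity_group == "DZ-FF"])
  expect_lt(abs(r_mz - 0.48), 0.01)
  expect_lt(abs(r_dz - 0.24), 0.01)
  # marginal liabilities stay standard normal
  expect_equal(mean(rec$liab2), 0, tolerance = 0.02)
  expect_equal(sd(rec$liab2), 1, tolerance = 0.01)
})

test_that("marginal status frequencies converge to the prevalences", {
  p <- sim_params(a2 = 0.47, e2 = 0.53,
                  prevalences = c(minor = 0.0898, major = 0.0205),
                  n_pairs = c("MZ-FF" = 5e4, "DZ-FF" = 5e4), seed = 5)
  rec <- simulate_cohort(p)
  s <- c(rec$status1, rec$status2)
  n <- length(s)
  for (target in list(c(2L, 0.0205), c(1L, 0.0898))) {
    phat <- mean(s == target[1])
    mc_se <- sqrt(target[2] * (1 - target[2]) / n)
    expect_lt(abs(phat - target[2]), 3 * mc_se)
  }
})

test_that("same-sex twin statuses are exchangeable in expectation", {
  p <- sim_params(a2 = 0.5, e2 = 0.5, n_pairs = c("MZ-FF" = 4e4,
                                                  "DZ-FF" = 4e4), seed = 17)
  rec <- simulate_cohort(p)
  # twin 1 and twin 2 marginal affection rates agree within MC error
  p1 <- mean(rec$status1 >= 1); p2 <- mean(rec$status2 >= 1)
  expect_lt(abs(p1 - p2), 3 * sqrt(p1 * (1 - p1) / nrow(rec) * 2))
})

test_that("symptom vectors are consistent with the assigned status", {
  p <- cohort_preset("aged", seed = 21)
  rec <- simulate_cohort(p, symptoms = TRUE)
  s1 <- as.matrix(rec[, paste0("sym", 1:9, "_1")])
  s2 <- as.matrix(rec[, paste0("sym", 1:9, "_2")])
  expect_identical(classify_dsm(s1), rec$status1)
  expect_identical(classify_dsm(s2), rec$status2)
})
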