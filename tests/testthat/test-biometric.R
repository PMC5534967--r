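test_that("pair log-likelihood factorizes when e2 = 1", {
  rec <- toy_records()
  thr <- c(0.8, 1.6)
  ll <- pair_loglik(rec, a2 = 0, thresholds = thr)
  bnds <- c(-Inf, thr, Inf)
  marg <- function(s) log(pnorm(bnds[s + 2]) - pnorm(bnds[s + 1]))
  expect_equal(ll, marg(rec$status1) + marg(rec$status2), tolerance = 1e-10)
})

test_that("pair log-likelihood matches dense numerical double integration", {
  set.seed(70)
  for (i in 1:50) {
    a2 <- runif(1, 0, 0.8); c2 <- runif(1, 0, 1 - a2 - 0.05)
    thr <- sort(runif(2, -1.5, 2))
    ba <- runif(1, -0.02, 0.02); bs <- runif(1, -0.3, 0.3)
    rec <- toy_records()[sample(1:6, 1), ]
    ll <- pair_loglik(rec, a2 = a2, c2 = c2, thresholds = thr,
                      beta_age = ba, beta_sex = bs, age_ref = 65)
    r <- if (startsWith(rec$zygosity_group, "MZ")) a2 + c2 else
      0.5 * a2 + c2
    bnds <- c(-Inf, thr, Inf)
    sh1 <- ba * (rec$age - 65) + bs * (rec$sex1 == "M")
    sh2 <- ba * (rec$age - 65) + bs * (rec$sex2 == "M")
    ref <- dense_rect_prob(bnds[rec$status1 + 1] + sh1,
                           bnds[rec$status1 + 2] + sh1,
                           bnds[rec$status2 + 1] + sh2,
                           bnds[rec$status2 + 2] + sh2, r)
    expect_equal(exp(ll), ref, tolerance = 1e-8)
  }
})

test_that("E model fixes the components and matches ordinal-probit ML", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 5))
  fit <- fit_biometric(rec, "E", classification = "three")
  expect_equal(unname(fit$estimates), c(0, 0, 0, 1))

  # with r = 0 the twin likelihood is two independent ordinal probits;
  # cross-check thresholds and deviance against MASS::polr
  skip_if_not_installed("MASS")
  long <- data.frame(
    status = factor(c(rec$status1, rec$status2), ordered = TRUE))
  pol <- MASS::polr(status ~ 1, data = long, method = "probit")
  expect_equal(fit$thresholds, unname(pol$zeta), tolerance = 1e-4)
  expect_equal(fit$minus2LL, pol$deviance, tolerance = 1e-4)

  # and with covariates the probit regression must agree too
  fitc <- fit_biometric(rec, "E", classification = "three",
                        covariates = c("age", "sex"))
  longc <- data.frame(
    status = factor(c(rec$status1, rec$status2), ordered = TRUE),
    age = c(rec$age, rec$age) - mean(rec$age),
    male = c(rec$sex1, rec$sex2) == "M")
  polc <- MASS::polr(status ~ age + male, data = longc, method = "probit")
  expect_equal(fitc$minus2LL, polc$deviance, tolerance = 1e-3)
  # thresholds shift by +beta per unit covariate <=> polr's -coef convention
  expect_equal(unname(fitc$betas["age"]), unname(-coef(polc)["age"]),
               tolerance = 1e-3)
})

test_that("AE parameter recovery on simulated cohorts", {
  p <- sim_params(a2 = 0.4, e2 = 0.6, thresholds = c(1.2249, 2.0433),
                  n_pairs = c("MZ-FF" = 5000, "DZ-FF" = 5000), seed = 101)
  rec <- simulate_cohort(p)
  fit <- fit_biometric(rec, "AE", classification = "three")
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$estimates["a2"]) - 0.4), 0.05)
  expect_equal(unname(fit$estimates["a2"] + fit$estimates["e2"]), 1,
               tolerance = 1e-8)
})

test_that("equal MZ and DZ correlations drive a2 to zero under ACE", {
  # common environment only: rMZ = rDZ = c2
  p <- sim_params(a2 = 0, c2 = 0.4, e2 = 0.6,
                  thresholds = c(1.2249, 2.0433),
                  n_pairs = c("MZ-FF" = 4000, "DZ-FF" = 4000), seed = 102)
  rec <- simulate_cohort(p)
  fit <- fit_biometric(rec, "ACE", classification = "three")
  expect_lt(unname(fit$estimates["a2"]), 0.1)
  expect_lt(abs(unname(fit$estimates["c2"]) - 0.4), 0.08)
})

test_that("fit is invariant to swapping twin labels in same-sex pairs", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 6))
  swap <- rec
  swap$status1 <- rec$status2
  swap$status2 <- rec$status1
  f1 <- fit_biometric(rec, "AE", classification = "two")
  f2 <- fit_biometric(swap, "AE", classification = "two")
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-5)
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-6)
})

test_that("nested deviances are monotone and LRT/AIC behave", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 7))
  lad <- compare_biometric(rec, "two")
  fits <- attr(lad, "fits")
  for (m in c("AE", "CE", "E"))
    expect_gte(fits[[m]]$minus2LL, fits[["ACE"]]$minus2LL - 1e-6)
  expect_gte(fits[["E"]]$minus2LL, fits[["AE"]]$minus2LL - 1e-6)

  lrt <- likelihood_ratio_test(fits[["ACE"]], fits[["E"]])
  expect_identical(lrt$df, 2L)
  expect_equal(lrt$chi2, fits[["E"]]$minus2LL - fits[["ACE"]]$minus2LL)
  expect_error(likelihood_ratio_test(fits[["AE"]], fits[["CE"]]),
               "not nested")

  # AIC: deviance plus twice the parameter count
  expect_equal(fits[["ACE"]]$aic,
               fits[["ACE"]]$minus2LL + 2 * fits[["ACE"]]$npar)
  expect_equal(fits[["ACE"]]$npar - fits[["AE"]]$npar, 1L)
  # equal deviance with one fewer parameter -> AIC difference exactly 2
  if (abs(fits[["AE"]]$minus2LL - fits[["ACE"]]$minus2LL) < 0.1)
    expect_lt(fits[["AE"]]$aic, fits[["ACE"]]$aic)
})

test_that("published deviance pairs reproduce the printed p-values", {
  pub <- published_deviances()
  expect_identical(nrow(pub), 9L)
  for (i in seq_len(nrow(pub))) {
    res <- lrt_from_deviance(pub$minus2LL_nested[i], pub$minus2LL_full[i],
                             pub$df[i])
    printed <- pub$printed_p[i]
    # agreement at the precision the value is printed to: two decimals for
    # plain p-values, two significant digits for scientific notation
    tol <- if (printed >= 0.01) 0.005 else
      0.5 * 10^(floor(log10(printed)) - 1)
    expect_lt(abs(res$p - printed), tol)
  }
  expect_equal(lrt_from_deviance(1460.62, 1446.58, 2)$p, 8.9e-4,
               tolerance = 0.01)
  expect_equal(lrt_from_deviance(476.73, 475.73, 1)$p, 0.32,
               tolerance = 0.01)
  # identical deviances -> no evidence
  eqv <- lrt_from_deviance(100, 100, 1)
  expect_equal(eqv$chi2, 0)
  expect_equal(eqv$p, 1)
})

test_that("profile CIs contain the estimate and clamp at boundaries", {
  p <- sim_params(a2 = 0.4, e2 = 0.6, thresholds = c(1.2249, 2.0433),
                  n_pairs = c("MZ-FF" = 1500, "DZ-FF" = 1500), seed = 103)
  rec <- simulate_cohort(p)
  fit <- fit_biometric(rec, "AE", classification = "two")
  ci <- profile_ci(fit, "a2")
  expect_lte(ci[1], fit$estimates[["a2"]])
  expect_gte(ci[2], fit$estimates[["a2"]])

  # a component at the boundary gets a lower bound of exactly 0
  p0 <- sim_params(a2 = 0, c2 = 0.4, e2 = 0.6,
                   thresholds = c(1.2249), age_range = c(50, 92),
                   n_pairs = c("MZ-FF" = 800, "DZ-FF" = 800), seed = 104)
  rec0 <- simulate_cohort(p0)
  f0 <- fit_biometric(rec0, "ACE", classification = "two")
  if (f0$estimates[["a2"]] < 1e-4) {
    ci0 <- profile_ci(f0, "a2")
    expect_identical(ci0[[1]], 0)
  }
})

test_that("two- and three-category fits agree on the same continuum data", {
  set.seed(105)
  diffs <- replicate(12, {
    rec <- simulate_cohort(cohort_preset("aged",
                                         seed = sample.int(1e6, 1)))
    a3 <- fit_biometric(rec, "AE", classification = "three")$estimates["a2"]
    a2 <- fit_biometric(rec, "AE", classification = "two")$estimates["a2"]
    a3 - a2
  })
  mc_se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * mc_se + 0.02)
})
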