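test_that("crosstab counts statuses and collapses categories", {
  rec <- toy_records()[1:3, ]
  rec$zygosity_group <- "MZ-FF"
  tab3 <- crosstab(rec, classification = "three")
  expect_equal(sum(tab3$counts), 3)
  expect_equal(tab3$counts[1, 1], 1)  # (0,0)
  expect_equal(tab3$counts[2, 3], 1)  # (1,2)
  expect_equal(tab3$counts[3, 2], 1)  # (2,1)
  tab2 <- crosstab(rec, classification = "two")
  expect_equal(tab2$counts, matrix(c(1, 0, 0, 2), 2, 2,
                                   dimnames = list(c("ND", "MiD/MD"),
                                                   c("ND", "MiD/MD"))))
  expect_error(crosstab(rec, groups = "DZ-MM"), "no pairs")
})

test_that("minor/major classifications drop the excluded category", {
  rec <- toy_records()
  tb <- crosstab(rec, classification = "minor", exclude = "pair")
  # pairs involving a major case are gone
  expect_equal(sum(tb$counts), 3)
  expect_equal(dim(tb$counts), c(2L, 2L))
  tb2 <- crosstab(rec, classification = "major", exclude = "pair")
  expect_equal(sum(tb2$counts), 3)
  expect_equal(dim(tb2$counts), c(2L, 2L))
})

test_that("symmetrize averages over proband choice", {
  t0 <- pair_table(matrix(c(0, 4, 2, 0), 2, 2), c("ND", "D"), "MZ-FF")
  s <- symmetrize(t0)
  expect_equal(s$counts, matrix(c(0, 3, 3, 0), 2, 2,
                                dimnames = dimnames(s$counts)))
  # idempotent on symmetric tables
  expect_equal(symmetrize(s)$counts, s$counts)
  # total preserved over random tables
  set.seed(4)
  for (i in 1:1000) {
    m <- matrix(rpois(9, 5), 3, 3)
    if (sum(m) == 0) next
    tt <- pair_table(m, zygosity_group = "DZ-FF")
    st <- symmetrize(tt)
    expect_equal(sum(st$counts), sum(m))
    expect_equal(st$counts, t(st$counts))
  }
  opp <- pair_table(matrix(1:4, 2, 2), c("ND", "D"), "DZ-FM",
                    opposite_sex = TRUE)
  expect_error(symmetrize(opp), "opposite-sex")
})

test_that("relative risk reproduces hand arithmetic and flags zeros", {
  tab <- pair_table(matrix(c(50, 20, 20, 10), 2, 2,
                           byrow = TRUE), c("ND", "D"), "MZ-FF")
  # condition row: 10/30 affected; reference row: 20/70
  rr <- relative_risk(tab, "D", "D")
  expect_equal(rr$rr, 7 / 6, tolerance = 1e-12)
  se <- sqrt(1 / 10 - 1 / 30 + 1 / 20 - 1 / 70)
  expect_equal(rr$ci_low, exp(log(7 / 6) - qnorm(0.975) * se),
               tolerance = 1e-10)
  expect_equal(rr$ci_high, exp(log(7 / 6) + qnorm(0.975) * se),
               tolerance = 1e-10)

  # equal risks in both rows -> RR 1
  eq <- pair_table(matrix(c(30, 10, 60, 20), 2, 2, byrow = TRUE),
                   c("ND", "D"))
  expect_equal(relative_risk(eq, "D", "D")$rr, 1, tolerance = 1e-12)

  # zero reference risk -> non-estimable, mirrored em-dash semantics
  z <- pair_table(matrix(c(40, 0, 5, 5), 2, 2, byrow = TRUE), c("ND", "D"))
  res <- relative_risk(z, "D", "D")
  expect_false(res$estimable)
  expect_match(res$reason, "reference")
  expect_error(relative_risk(tab, "ND", "D"), "reference category")
})

test_that("Katz interval is consistent with a bootstrap over the table", {
  counts <- matrix(c(120, 30, 25, 25), 2, 2, byrow = TRUE)
  tab <- pair_table(counts, c("ND", "D"))
  rr <- relative_risk(tab, "D", "D")
  set.seed(8)
  boot <- replicate(4000, {
    r0 <- rbinom(1, 150, 30 / 150)
    r1 <- rbinom(1, 50, 25 / 50)
    if (r0 == 0 || r1 == 0) NA else (r1 / 50) / (r0 / 150)
  })
  lb <- quantile(log(boot), c(0.025, 0.975), na.rm = TRUE)
  # log-scale endpoints agree with the percentile bootstrap to ~10%
  expect_equal(log(rr$ci_low), unname(lb[1]), tolerance = 0.1)
  expect_equal(log(rr$ci_high), unname(lb[2]), tolerance = 0.1)
})

test_that("confidence interval coverage is nominal over simulated tables", {
  set.seed(12)
  p1 <- 0.4; p0 <- 0.2; n1 <- 80; n0 <- 160
  true_rr <- p1 / p0
  cover <- logical(600)
  for (i in seq_along(cover)) {
    x1 <- rbinom(1, n1, p1); x0 <- rbinom(1, n0, p0)
    tab <- pair_table(matrix(c(n0 - x0, x0, n1 - x1, x1), 2, 2,
                             byrow = TRUE), c("ND", "D"))
    rr <- relative_risk(tab, "D", "D")
    cover[i] <- rr$estimable && rr$ci_low <= true_rr && true_rr <= rr$ci_high
  }
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("familial clustering is stronger in MZ than DZ pairs on average", {
  set.seed(31)
  ratios <- replicate(30, {
    rec <- simulate_cohort(cohort_preset("aged",
                                         seed = sample.int(1e6, 1)))
    mz <- symmetrize(crosstab(rec, c("MZ-FF", "MZ-MM"), "two"))
    dz <- symmetrize(crosstab(rec, c("DZ-FF", "DZ-MM"), "two"))
    c(relative_risk(mz, 2, 2)$rr, relative_risk(dz, 2, 2)$rr)
  })
  expect_gt(mean(ratios[1, ], na.rm = TRUE), mean(ratios[2, ], na.rm = TRUE))
})

test_that("rr_table lays out the full condition-outcome grid", {
  rec <- simulate_cohort(cohort_preset("aged", seed = 2))
  grid <- rr_table(rec)
  expect_identical(nrow(grid), 9L)
  expect_identical(names(grid)[-1],
                   c("MZ", "DZss", "DZos F-M", "DZos M-F"))
  expect_true(all(grepl("^([0-9.]+ \\([0-9.]+-[0-9.]+\\)|—)$",
                        unlist(grid[, -1]))))
  # opposite-sex pooling: 136 + 105 pairs in each orientation
  tabs <- attr(grid, "tables")
  expect_equal(sum(tabs[["DZos F-M"]]$counts), 241)
  expect_equal(sum(tabs[["DZos M-F"]]$counts), 241)
})
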