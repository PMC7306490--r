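test_that("rank-sum test: exact small-sample behavior against enumeration", {
  # identical multisets: no evidence of a shift
  expect_gte(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)

  # the classic fully separated 3 vs 3 case: one-sided tail 1/20
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  # exact mode matches enumeration for arbitrary small tie-free splits
  set.seed(31)
  for (rep in 1:6) {
    na <- sample(2:4, 1)
    vals <- sample(seq(0.1, 9.9, by = 0.1), na + 4)
    a <- vals[seq_len(na)]
    b <- vals[-seq_len(na)]
    expect_equal(ranksum_test(a, b)$p_value, enum_ranksum_p(a, b),
                 tolerance = 1e-12)
  }

  # asymptotic sanity: a 1 SD shift at n = 200 is overwhelming
  set.seed(32)
  expect_lt(ranksum_test(rnorm(200), rnorm(200) + 1)$p_value, 1e-10)

  expect_error(ranksum_test(rep(2, 5), rep(2, 5)), "identical")
  expect_error(ranksum_test(1, c(2, 3)), ">= 2")
})

test_that("significance tiers follow the 0.05 / 0.01 / 0.001 convention", {
  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.0009)),
               c("", "*", "**", "***"))
})

test_that("BH adjustment reproduces the published table in the plain dialect", {
  tab <- published_bh_table()
  m <- nrow(tab)
  for (fam in c("mccc", "delay")) {
    p <- tab[[paste0(fam, "_p")]]
    printed <- tab[[paste0(fam, "_adj")]]
    adj <- bh_adjust(p, dialect = "plain")
    r <- rank(p, ties.method = "first")
    # tolerance: half a display unit of the printed adjusted value plus
    # the propagated rounding of the printed input p-value
    tol <- half_ulp(printed) + half_ulp(p) * m / r
    expect_true(all(abs(adj - printed) <= tol),
                info = paste(fam, "family"))
  }
  # spot values at display precision
  adj_m <- bh_adjust(tab$mccc_p, "plain")
  expect_equal(signif(adj_m[tab$pair == "LE-RE"], 3), 2.96e-30)
  expect_lt(abs(adj_m[tab$pair == "RF-LT"] - 0.050), 1e-3)
  adj_d <- bh_adjust(tab$delay_p, "plain")
  expect_equal(signif(adj_d[tab$pair == "RF-LT"], 3), 1.02e-7)
})

test_that("BH dialects differ exactly where the step-up pass bites", {
  tab <- published_bh_table()
  up <- bh_adjust(tab$mccc_p, dialect = "step_up")
  # step-up pulls LE-LF down to the later-ranked RE-LF value
  expect_equal(round(up[tab$pair == "LE-LF"], 3), 0.562)
  expect_identical(up, p.adjust(tab$mccc_p, method = "BH"))

  expect_equal(bh_adjust(0.37, "plain"), 0.37)
  expect_equal(bh_adjust(0.37, "step_up"), 0.37)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("group comparison: family bookkeeping and null behavior", {
  set.seed(33)
  feats <- data.frame(matrix(rnorm(40 * 11), 40))
  names(feats) <- paste0("f", 1:11)
  labels <- rep(c("healthy", "stroke"), each = 20)
  out <- compare_groups(feats, labels)
  expect_equal(nrow(out), 11)
  # family size 11 used in the adjustment
  r <- rank(out$p_value, ties.method = "first")
  expect_equal(out$adjusted_p, out$p_value * 11 / r)
  # identical-distribution groups: nothing significant after adjustment
  expect_gt(min(out$adjusted_p), 0.05)

  expect_error(compare_groups(feats, labels, columns = "nope"), "nope")
})

test_that("LE-path embolism degrades LE-RE correlation but not LT-RT", {
  fx <- le_cohort_fixture()
  cmp <- fx$analysis$comparisons
  expect_equal(nrow(cmp), 11)
  expect_lt(cmp$mccc_adjusted_p[cmp$pair == "LE-RE"], 0.05)
  expect_gt(cmp$mccc_adjusted_p[cmp$pair == "LT-RT"], 0.05)
})
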