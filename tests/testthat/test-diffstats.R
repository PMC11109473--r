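# independent enumeration oracle: two-sided p of a statistic over all
# C(nA+nB, nA) group-A labelings, written against the pooled data directly
enumerate_p <- function(a, b, stat_fn) {
  pooled <- c(a, b)
  n <- length(pooled); nA <- length(a)
  t_obs <- stat_fn(a, b)
  combos <- combn(n, nA)
  t_all <- apply(combos, 2, function(idx)
    stat_fn(pooled[idx], pooled[-idx]))
  mean(abs(t_all) >= abs(t_obs) - 1e-12 * max(1, abs(t_obs)))
}

test_that("identical groups give p = 1 for rank and permutation tests", {
  x <- c(1, 2, 3)
  expect_equal(pairwise_test(x, x, "mann_whitney")$p_value, 1)
  expect_equal(pairwise_test(x, x, "wilcoxon_rank_sum")$p_value, 1)
  expect_equal(permutation_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  expect_equal(pairwise_test(x, x, "wilcoxon_signed_rank")$p_value, 1)
})

test_that("exact rank-sum p matches exhaustive enumeration of labelings", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- pairwise_test(a, b, "wilcoxon_rank_sum")
  expect_true(res$exact)
  # rank-sum statistic enumerated over all C(6,3) = 20 labelings
  oracle <- enumerate_p(a, b, function(x, y) sum(rank(c(x, y))[1:3]) - 3 * 7 / 2)
  expect_equal(res$p_value, oracle)
  expect_equal(res$p_value, 0.1) # most extreme split: 2/20
  expect_lt(res$statistic, 0)    # oriented A over B
})

test_that("statistic signs are oriented so positive means A above B", {
  lo <- c(1, 2, 3); hi <- c(10, 11, 12)
  for (test in c("t_test", "mann_whitney", "wilcoxon_rank_sum",
                 "permutation")) {
    expect_gt(pairwise_test(hi, lo, test, seed = 1)$statistic, 0)
    expect_lt(pairwise_test(lo, hi, test, seed = 1)$statistic, 0)
  }
  expect_gt(pairwise_test(hi, lo, "wilcoxon_signed_rank")$statistic, 0)
})

test_that("permutation test enumerates exhaustively at small n", {
  a <- c(1, 2, 3); b <- c(7, 8, 9)
  res <- permutation_test(a, b, statistic = "mean_diff")
  expect_true(res$exact)
  expect_identical(res$n_used, 20)
  expect_equal(res$p_value, 2 / 20) # both extreme assignments
  expect_equal(res$statistic, -6)
})

test_that("exhaustive permutation p equals the enumeration oracle exactly", {
  set.seed(52)
  for (nA in 2:4) for (nB in 2:4) {
    a <- rnorm(nA); b <- rnorm(nB, mean = 1)
    res <- permutation_test(a, b, statistic = "mean_diff")
    expect_true(res$exact)
    expect_equal(res$p_value,
                 enumerate_p(a, b, function(x, y) mean(x) - mean(y)),
                 tolerance = 1e-12,
                 label = sprintf("p at nA=%d nB=%d", nA, nB))
  }
  # rank_sum statistic route as well (centered at the null mean)
  a <- c(2.2, 3.1, 1.4, 0.8); b <- c(4.0, 5.5, 3.9, 4.4)
  rank_stat <- function(x, y) {
    n <- length(x) + length(y)
    sum(rank(c(x, y))[seq_along(x)]) - length(x) * (n + 1) / 2
  }
  expect_equal(permutation_test(a, b, statistic = "rank_sum")$p_value,
               enumerate_p(a, b, rank_stat), tolerance = 1e-12)
})

test_that("Monte-Carlo permutation p is deterministic under a seed", {
  set.seed(61)
  a <- rnorm(12); b <- rnorm(12, 0.5)
  r1 <- permutation_test(a, b, n_permutations = 2000, seed = 99)
  r2 <- permutation_test(a, b, n_permutations = 2000, seed = 99)
  expect_false(r1$exact) # choose(24,12) >> 2000
  expect_identical(r1$p_value, r2$p_value)
  # add-one rule keeps p strictly positive and bounded
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  r3 <- permutation_test(a, b, n_permutations = 2000, seed = 100)
  expect_false(identical(r1$p_value, 0)) # sanity on the rule, not the seed
  expect_error(permutation_test(a, b, n_permutations = 50), "at least 100")
})

test_that("Kruskal-Wallis H matches the tie-free rank formula", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  res <- multigroup_test(groups)
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 with ranks 1..6
  rbar <- c(1.5, 3.5, 5.5)
  h <- 12 / (6 * 7) * sum(2 * (rbar - 3.5)^2)
  expect_equal(res$statistic, h, tolerance = 1e-12)
  expect_identical(res$df, 2L)

  ident <- multigroup_test(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$p_value, 1, tolerance = 1e-9)
  expect_equal(ident$statistic, 0, tolerance = 1e-9)

  expect_error(multigroup_test(list(1:3, 4:6)), "at least 3")
  skip <- multigroup_test(list(1:3, 4:6, c(NA_real_, NA_real_)))
  expect_true(skip$skipped)
})

test_that("BH adjustment matches the hand step-up and an independent oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03) # m = 1 identity

  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    # step-up: smallest adjusted value from the top; (m/i)*p association
    # so floating-point results are comparable bit-for-bit
    stepped <- (m / seq_len(m)) * p[o]
    adj <- rev(cummin(rev(stepped)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  set.seed(71)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_identical(adjust_pvalues(p, "BH"), bh_oracle(p))
  }
  # NA passthrough and method registry
  expect_identical(adjust_pvalues(c(0.5, NA))[2], NA_real_)
  expect_error(adjust_pvalues(0.5, "nope"), "supported methods")
  expect_identical(adjust_pvalues(c(0.2, 0.01), "none"), c(0.2, 0.01))
})

test_that("features with too few observations are skipped with a reason", {
  res <- pairwise_test(c(1, NA, NA), c(2, 3, 4), "t_test")
  expect_true(res$skipped)
  expect_identical(res$reason, "insufficient_observations")
  expect_true(pairwise_test(c(1, 2), c(3, 4, 5), "wilcoxon_signed_rank")$skipped)
  expect_true(permutation_test(c(1), c(2, 3))$skipped)
})

test_that("run_comparison applies per-quantity tests and FDR families", {
  ds <- small_dataset()
  spec <- comparison_spec(
    "pairwise_condition",
    groups = list(list(condition = "KO"), list(condition = "Control")),
    alpha = 0.05, seed = 5)
  res <- run_comparison(ds, spec)
  expect_setequal(unique(res$quantity),
                  c("abundance", "fractional", "isotopologue"))
  # BH applied within each (comparison x quantity) family
  for (q in unique(res$quantity)) {
    sub <- res[res$quantity == q, ]
    expect_identical(sub$p_adj, adjust_pvalues(sub$p_raw, "BH"))
  }
  # determinism: same spec, same seed -> identical table
  expect_identical(res, run_comparison(ds, spec))

  # family isolation: dropping isotopologues leaves abundance rows unchanged
  ds2 <- ds
  ds2$isotopologue_prop <- NULL
  res2 <- run_comparison(ds2, spec)
  expect_identical(res2[res2$quantity == "abundance", ],
                   res[res$quantity == "abundance", ])

  # alpha -> 0+ yields no DAMs
  spec0 <- comparison_spec(
    "pairwise_condition",
    groups = list(list(condition = "KO"), list(condition = "Control")),
    alpha = 1e-12, seed = 5)
  expect_identical(sum(run_comparison(ds, spec0)$significant), 0L)

  # empty selector is a specification error naming the group
  bad <- comparison_spec(
    "pairwise_condition",
    groups = list(list(condition = "Missing"), list(condition = "Control")))
  expect_error(run_comparison(ds, bad), "Missing")
})

test_that("effect sizes follow the per-quantity convention", {
  ds <- small_dataset()
  spec <- comparison_spec(
    "pairwise_condition",
    groups = list(list(condition = "KO"), list(condition = "Control")),
    seed = 5)
  res <- run_comparison(ds, spec)
  ab <- res[res$quantity == "abundance", ]
  ko <- resolve_samples(ds$sample_sheet, list(condition = "KO"))
  ctl <- resolve_samples(ds$sample_sheet, list(condition = "Control"))
  for (i in seq_len(nrow(ab))) {
    va <- ds$abundance$values[ab$feature_id[i], ko]
    vb <- ds$abundance$values[ab$feature_id[i], ctl]
    expect_equal(ab$effect[i], mean(log2(va)) - mean(log2(vb)),
                 tolerance = 1e-12)
  }
  fr <- res[res$quantity == "fractional", ]
  for (i in seq_len(nrow(fr))) {
    va <- ds$fractional$values[fr$feature_id[i], ko]
    vb <- ds$fractional$values[fr$feature_id[i], ctl]
    expect_equal(fr$effect[i], mean(va) - mean(vb), tolerance = 1e-12)
  }
})

test_that("multigroup comparisons demand Kruskal-Wallis and >= 3 groups", {
  expect_error(comparison_spec("multigroup",
                               groups = list(list(condition = "a"),
                                             list(condition = "b"))),
               "at least 3")
  expect_error(comparison_spec("multigroup",
                               groups = list(list(condition = "a"),
                                             list(condition = "b"),
                                             list(condition = "c"))),
               "kruskal_wallis")
  kw <- list(abundance = "kruskal_wallis", fractional = "kruskal_wallis",
             isotopologue = "kruskal_wallis")
  expect_s3_class(comparison_spec("multigroup",
                                  groups = list(list(condition = "a"),
                                                list(condition = "b"),
                                                list(condition = "c")),
                                  tests = kw),
                  "ComparisonSpec")
})

test_that("consecutive time points yield T-1 ordered families", {
  spec <- fixture_spec(metabolites = c(akg = 3), conditions = "Control",
                       timepoints_h = c(0, 1, 2, 4, 6, 24), replicates = 3,
                       noise_cv = 0.2, seed = 9)
  ds <- generate_dataset(spec)$dataset
  res <- timecourse_comparisons(ds, test = "t_test", seed = 2)
  expect_identical(attr(res, "comparisons"),
                   c("1vs0", "2vs1", "4vs2", "6vs4", "24vs6"))
  expect_identical(length(unique(res$comparison)), 5L)

  # two timepoints -> a single family
  spec2 <- fixture_spec(metabolites = c(akg = 3), timepoints_h = c(0, 24),
                        replicates = 3, seed = 9)
  res2 <- timecourse_comparisons(generate_dataset(spec2)$dataset,
                                 test = "t_test", seed = 2)
  expect_identical(attr(res2, "comparisons"), "24vs0")
})
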