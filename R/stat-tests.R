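#' Catalog of offered univariate tests
#'
#' The engine offers parametric and nonparametric two-group tests plus the
#' Kruskal-Wallis multi-group test; nonparametric options matter because
#' tracer metabolomics data are rarely Gaussian and group sizes are small
#' (typically triplicates). `mann_whitney` and `wilcoxon_rank_sum` are two
#' names for the same unpaired rank test and are both accepted.
#'
#' @return tibble with columns `name`, `paired`, `min_group_size`, `arity`.
#' @export
test_catalog <- function() {
  tibble::tibble(
    name = c("t_test", "mann_whitney", "wilcoxon_signed_rank",
             "wilcoxon_rank_sum", "kruskal_wallis", "permutation"),
    paired = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    min_group_size = c(2L, 2L, 2L, 2L, 2L, 2L),
    arity = c("2", "2", "2", "2", ">=2", "2")
  )
}

assert_known_test <- function(test) {
  if (!test %in% test_catalog()$name) {
    abort_aggregate(test_catalog()$name,
                    sprintf('unknown test "%s"; supported tests', test))
  }
  test
}

skip_result <- function(reason) {
  list(statistic = NA_real_, p_value = NA_real_, exact = NA,
       skipped = TRUE, reason = reason)
}

#' Two-group test of one feature
#'
#' Runs the selected test on two sample vectors after missing-value removal
#' (pairwise-complete; paired tests drop incomplete pairs). The returned
#' statistic is oriented so that a positive value means group A is located
#' above group B. Two-sided p-values throughout. Rank tests use the exact
#' null distribution when both groups have at most `exact_threshold`
#' observations and there are no ties, the normal approximation with
#' continuity and tie correction otherwise (the `stats::wilcox.test`
#' behaviour). Features with too few observations are skipped with a reason
#' code, never a silent `NaN`.
#'
#' @param a,b numeric vectors (group A and group B); for paired tests they
#'   must be replicate-aligned and of equal length.
#' @param test a name from [test_catalog()].
#' @param n_permutations,perm_statistic,seed passed to [permutation_test()]
#'   when `test = "permutation"`.
#' @param exact_threshold largest group size for which rank tests use the
#'   exact null (default 25).
#' @return list with `statistic`, `p_value`, `exact` (logical or NA),
#'   `skipped`, `reason`.
#' @export
#' @examples
#' pairwise_test(c(1, 2, 3), c(4, 5, 6), "wilcoxon_rank_sum")$p_value
pairwise_test <- function(a, b, test = "t_test", n_permutations = 10000,
                          perm_statistic = "mean_diff", seed = NULL,
                          exact_threshold = 25) {
  assert_known_test(test)
  if (test == "kruskal_wallis") {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(skip_result("insufficient_observations"))
    }
    kt <- kruskal.test(list(a, b))
    sgn <- sign(mean(rank(c(a, b))[seq_along(a)]) -
                  mean(rank(c(a, b))[-seq_along(a)]))
    return(list(statistic = unname(kt$statistic) * ifelse(sgn == 0, 1, sgn),
                p_value = max(min(kt$p.value, 1), .Machine$double.xmin),
                exact = FALSE, skipped = FALSE, reason = NA_character_))
  }
  if (test == "wilcoxon_signed_rank") {
    if (length(a) != length(b)) {
      return(skip_result("paired_test_unequal_group_sizes"))
    }
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) < 2) return(skip_result("insufficient_observations"))
    d <- a - b
    if (all(d == 0)) {
      return(list(statistic = 0, p_value = 1, exact = TRUE,
                  skipped = FALSE, reason = NA_character_))
    }
    exact <- length(a) <= exact_threshold && !any(d == 0) &&
      !anyDuplicated(abs(d[d != 0]))
    wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = exact,
                                       correct = TRUE))
    m <- sum(d != 0)
    return(list(statistic = unname(wt$statistic) - m * (m + 1) / 4,
                p_value = max(min(wt$p.value, 1), .Machine$double.xmin),
                exact = exact, skipped = FALSE, reason = NA_character_))
  }
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  min_n <- if (test == "permutation") 2L else 2L
  if (length(a) < min_n || length(b) < min_n ||
      (test == "permutation" && length(a) + length(b) < 4)) {
    return(skip_result("insufficient_observations"))
  }
  switch(test,
    t_test = {
      if (sd(a) == 0 && sd(b) == 0) {
        p <- if (mean(a) == mean(b)) 1 else NA_real_
        if (is.na(p)) return(skip_result("zero_variance"))
        return(list(statistic = 0, p_value = 1, exact = FALSE,
                    skipped = FALSE, reason = NA_character_))
      }
      tt <- t.test(a, b, var.equal = TRUE)
      list(statistic = unname(tt$statistic),
           p_value = max(min(tt$p.value, 1), .Machine$double.xmin),
           exact = FALSE, skipped = FALSE, reason = NA_character_)
    },
    mann_whitney = ,
    wilcoxon_rank_sum = {
      exact <- max(length(a), length(b)) <= exact_threshold &&
        !anyDuplicated(c(a, b))
      wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
      list(statistic = unname(wt$statistic) - length(a) * length(b) / 2,
           p_value = max(min(wt$p.value, 1), .Machine$double.xmin),
           exact = exact, skipped = FALSE, reason = NA_character_)
    },
    permutation = {
      permutation_test(a, b, n_permutations = n_permutations,
                       statistic = perm_statistic, seed = seed)
    })
}

#' Two-group permutation test
#'
#' Tests the null of exchangeability between groups by permuting group
#' labels. When the number of distinct labelings `choose(nA + nB, nA)` does
#' not exceed `n_permutations`, the complete labeling set is enumerated and
#' the p-value is exact (`exact = TRUE`); otherwise `n_permutations` random
#' labelings are drawn and the add-one rule
#' `p = (1 + #\{|T*| >= |T_obs|\}) / (1 + n_permutations)` guarantees
#' `p > 0`. Two-sided via the absolute statistic.
#'
#' @param a,b numeric vectors; missing values removed.
#' @param n_permutations number of random labelings (>= 100).
#' @param statistic `"mean_diff"` (difference of group means, the default),
#'   `"abs_mean_diff"`, or `"rank_sum"` (midrank sum of group A).
#' @param seed optional integer; Monte-Carlo draws are reproducible for a
#'   fixed seed and the caller's RNG state is left untouched.
#' @return list with `statistic` (observed, signed for `mean_diff`),
#'   `p_value`, `exact`, `n_used` (labelings evaluated), `skipped`,
#'   `reason`.
#' @export
#' @examples
#' permutation_test(c(1, 2, 3), c(7, 8, 9), statistic = "mean_diff")
permutation_test <- function(a, b, n_permutations = 10000,
                             statistic = c("mean_diff", "abs_mean_diff",
                                           "rank_sum"),
                             seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_permutations < 100) {
    stop("n_permutations must be at least 100", call. = FALSE)
  }
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  nA <- length(a); nB <- length(b)
  if (nA < 1 || nB < 1 || nA + nB < 4) {
    return(skip_result("insufficient_observations"))
  }
  pooled <- c(a, b)
  n <- nA + nB
  # every offered statistic is an affine function of the group-A subset sum;
  # the rank sum is centered at its null mean so |T| is two-sided symmetric
  stat_from_sumA <- function(sumA, values_total) {
    md <- sumA / nA - (values_total - sumA) / nB
    switch(statistic,
           mean_diff = md,
           abs_mean_diff = abs(md),
           rank_sum = sumA - nA * (n + 1) / 2)
  }
  values <- if (statistic == "rank_sum") rank(pooled) else pooled
  total <- sum(values)
  t_obs <- stat_from_sumA(sum(values[seq_len(nA)]), total)
  tol <- 1e-12 * max(1, abs(t_obs)) # tie tolerance for FP-equal statistics
  n_distinct <- choose(n, nA)
  if (n_distinct <= n_permutations) {
    sums <- colSums(matrix(values[combn(n, nA)], nrow = nA))
    t_perm <- stat_from_sumA(sums, total)
    p <- sum(abs(t_perm) >= abs(t_obs) - tol) / n_distinct
    exact <- TRUE
    n_used <- n_distinct
  } else {
    sums <- with_seed(seed, perm_subset_sums(values, nA, n_permutations))
    t_perm <- stat_from_sumA(sums, total)
    p <- (1 + sum(abs(t_perm) >= abs(t_obs) - tol)) / (1 + n_permutations)
    exact <- FALSE
    n_used <- n_permutations
  }
  list(statistic = t_obs, p_value = min(p, 1), exact = exact,
       n_used = n_used, skipped = FALSE, reason = NA_character_)
}

#' Kruskal-Wallis multi-group test
#'
#' Nonparametric alternative to one-way ANOVA for comparing three or more
#' groups at once; appropriate when normality and homoscedasticity cannot
#' be assumed and group sizes are small. Uses the tie-corrected H statistic
#' with a chi-squared reference on k - 1 degrees of freedom.
#'
#' @param groups list of >= 3 numeric vectors.
#' @return list with `statistic` (H), `p_value`, `df`, `skipped`, `reason`.
#' @export
multigroup_test <- function(groups) {
  stopifnot(is.list(groups))
  if (length(groups) < 3) {
    stop("multi-group analysis needs at least 3 groups; use pairwise_test for 2",
         call. = FALSE)
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 1L) < 2)) {
    return(c(skip_result("group_with_fewer_than_2_observations"),
             list(df = NA_integer_)))
  }
  kt <- kruskal.test(groups)
  list(statistic = unname(kt$statistic),
       p_value = max(min(kt$p.value, 1), .Machine$double.xmin),
       df = unname(kt$parameter), skipped = FALSE, reason = NA_character_)
}

# registry of accepted FDR / FWER method names -> stats::p.adjust codes
fdr_method_registry <- function() {
  c(BH = "BH", "benjamini-hochberg" = "BH", fdr_bh = "BH",
    BY = "BY", "benjamini-yekutieli" = "BY",
    bonferroni = "bonferroni", holm = "holm", hochberg = "hochberg",
    hommel = "hommel", none = "none")
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up by default; other step-up/step-down methods
#' are resolved through an internal registry (`BH`, `BY`, `bonferroni`,
#' `holm`, `hochberg`, `hommel`, `none`). Missing entries pass through as
#' missing and do not count toward the family size.
#'
#' @param p numeric vector of raw p-values in `(0, 1]` (NAs allowed).
#' @param method a registry name (case-insensitive).
#' @return numeric vector of adjusted p-values, clipped to `<= 1`.
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH")
adjust_pvalues <- function(p, method = "BH") {
  registry <- fdr_method_registry()
  key <- names(registry)[match(tolower(method), tolower(names(registry)))]
  if (is.na(key)) {
    abort_aggregate(names(registry),
                    sprintf('unknown FDR method "%s"; supported methods', method))
  }
  ok <- !is.na(p)
  if (any(p[ok] <= 0 | p[ok] > 1)) {
    stop("raw p-values must lie in (0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- pmin(p.adjust(p[ok], method = registry[[key]]), 1)
  out
}
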