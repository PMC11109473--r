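#' Specify one statistical comparison
#'
#' @param kind `"pairwise_condition"` (two groups), `"consecutive_timepoints"`
#'   (handled by [timecourse_comparisons()]), or `"multigroup"` (>= 3
#'   groups, Kruskal-Wallis required).
#' @param groups ordered list of selectors, each a list with optional
#'   `condition` and `timepoint` entries (see [resolve_samples()]). For
#'   pairwise kinds the first group is the test group A, the second the
#'   reference B; effects and statistics are oriented A over B.
#' @param name label for the comparison; defaults to `"A_vs_B"` built from
#'   the group selectors.
#' @param tests named list mapping quantity type (`abundance`,
#'   `fractional`, `isotopologue`) to a [test_catalog()] name. Defaults
#'   follow the engine's per-quantity convention: permutation tests for
#'   abundances and fractional contributions, Wilcoxon rank-sum for
#'   isotopologue proportions.
#' @param correction FDR method name (see [adjust_pvalues()]).
#' @param alpha significance level on adjusted p-values, in (0, 1).
#' @param n_permutations permutation count for permutation tests.
#' @param seed top-level seed; per-feature sub-seeds are derived from it.
#' @return a `ComparisonSpec` list.
#' @export
comparison_spec <- function(kind = c("pairwise_condition", "multigroup",
                                     "consecutive_timepoints"),
                            groups, name = NULL,
                            tests = list(), correction = "BH", alpha = 0.05,
                            n_permutations = 10000, seed = 123) {
  kind <- match.arg(kind)
  stopifnot(is.list(groups), is.numeric(alpha), alpha > 0, alpha < 1)
  defaults <- list(abundance = "permutation", fractional = "permutation",
                   isotopologue = "wilcoxon_rank_sum")
  tests <- modifyList(defaults, as.list(tests))
  lapply(unlist(tests), assert_known_test)
  if (kind == "pairwise_condition" && length(groups) != 2) {
    stop("pairwise comparisons take exactly 2 groups", call. = FALSE)
  }
  if (kind == "multigroup") {
    if (length(groups) < 3) {
      stop("multigroup comparisons need at least 3 groups", call. = FALSE)
    }
    if (!all(unlist(tests) == "kruskal_wallis")) {
      stop("multigroup comparisons require the kruskal_wallis test",
           call. = FALSE)
    }
  }
  if (is.null(name)) {
    name <- paste(vapply(groups, group_label, ""), collapse = "_vs_")
  }
  structure(list(kind = kind, groups = groups, name = name, tests = tests,
                 correction = correction, alpha = alpha,
                 n_permutations = n_permutations, seed = seed),
            class = "ComparisonSpec")
}

dataset_quantity_matrices <- function(dataset,
                                      quantities = c("abundance",
                                                     "fractional",
                                                     "isotopologue")) {
  out <- list()
  if ("abundance" %in% quantities && !is.null(dataset$abundance)) {
    out$abundance <- dataset$abundance$values
  }
  if ("fractional" %in% quantities && !is.null(dataset$fractional)) {
    out$fractional <- dataset$fractional$values
  }
  if ("isotopologue" %in% quantities && !is.null(dataset$isotopologue_prop)) {
    out$isotopologue <- dataset$isotopologue_prop$values
  }
  out
}

# effect size convention: log2 ratio of geometric means for (strictly
# positive) abundances; difference of means for bounded quantities.
effect_size <- function(a, b, quantity) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  if (quantity == "abundance") {
    if (any(a <= 0) || any(b <= 0)) return(NA_real_)
    (mean(log2(a)) - mean(log2(b)))
  } else {
    mean(a) - mean(b)
  }
}

run_family <- function(values, samples_by_group, quantity, test, label,
                       correction, alpha, n_permutations, seed) {
  features <- rownames(values)
  rows <- lapply(features, function(f) {
    gvals <- lapply(samples_by_group, function(s) values[f, s])
    if (length(gvals) == 2) {
      res <- pairwise_test(gvals[[1]], gvals[[2]], test = test,
                           n_permutations = n_permutations,
                           seed = derive_seed(seed, f, quantity, label))
      eff <- if (res$skipped) NA_real_ else
        effect_size(gvals[[1]], gvals[[2]], quantity)
      tibble::tibble(feature_id = f, quantity = quantity, comparison = label,
                     mean_A = mean(gvals[[1]], na.rm = TRUE),
                     mean_B = mean(gvals[[2]], na.rm = TRUE),
                     effect = eff, statistic = res$statistic,
                     p_raw = res$p_value,
                     reason = res$reason %||% NA_character_)
    } else {
      res <- multigroup_test(gvals)
      tibble::tibble(feature_id = f, quantity = quantity, comparison = label,
                     mean_A = NA_real_, mean_B = NA_real_, effect = NA_real_,
                     statistic = res$statistic, p_raw = res$p_value,
                     reason = res$reason %||% NA_character_)
    }
  })
  out <- dplyr::bind_rows(rows)
  # one multiple-testing family per (comparison x quantity type)
  out$p_adj <- adjust_pvalues(out$p_raw, correction)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

#' Run one configured comparison over every quantity type of a dataset
#'
#' Applies the per-quantity test to each feature (metabolite, or
#' metabolite isotopologue for proportion data), computes effect sizes
#' (log2 ratio of geometric means for abundances, difference of means for
#' fractional contributions and proportions), and adjusts p-values within
#' each (comparison x quantity type) family — families never mix quantity
#' types, so abundance results are unaffected by isotopologue features. A
#' feature significant after adjustment (`p_adj <= alpha`) is a
#' differentially abundant/labeled metabolite (DAM).
#'
#' @param dataset a `TracerDataset` from [harmonize_inputs()] or
#'   [generate_dataset()].
#' @param spec a [comparison_spec()].
#' @param quantities subset of `c("abundance", "fractional",
#'   "isotopologue")` to analyse (defaults to all present).
#' @return tibble with columns `feature_id`, `quantity`, `comparison`,
#'   `mean_A`, `mean_B`, `effect`, `statistic`, `p_raw`, `p_adj`,
#'   `significant`, `reason`.
#' @export
run_comparison <- function(dataset, spec,
                           quantities = c("abundance", "fractional",
                                          "isotopologue")) {
  stopifnot(inherits(dataset, "TracerDataset"),
            inherits(spec, "ComparisonSpec"))
  sheet <- dataset$sample_sheet
  samples_by_group <- lapply(spec$groups, function(g) resolve_samples(sheet, g))
  empty <- vapply(samples_by_group, length, 1L) == 0
  if (any(empty)) {
    abort_aggregate(vapply(spec$groups[empty], group_label, ""),
                    "comparison group selectors resolving to zero samples")
  }
  mats <- dataset_quantity_matrices(dataset, quantities)
  fams <- lapply(names(mats), function(q) {
    keep <- lapply(samples_by_group, function(s)
      intersect(s, colnames(mats[[q]])))
    run_family(mats[[q]], keep, q, spec$tests[[q]], spec$name,
               spec$correction, spec$alpha, spec$n_permutations, spec$seed)
  })
  dplyr::bind_rows(fams)
}

#' Automatic consecutive time-point comparisons
#'
#' For an ordered series of time points t1 < t2 < ... < tT (hours), builds
#' the T - 1 comparison families t_{i+1} versus t_i (later time point as
#' group A) and tests every feature in each family; p-values are adjusted
#' within each (family x quantity type). A feature is time-responsive when
#' it is significant in at least one family (see
#' [time_responsive_features()]).
#'
#' @param dataset a `TracerDataset`.
#' @param condition optional condition to restrict to (needed when the
#'   sheet contains several).
#' @param test test name applied to every quantity type (default Wilcoxon
#'   rank-sum), or a named per-quantity list as in [comparison_spec()].
#' @param quantities quantity types to analyse.
#' @param correction,alpha,n_permutations,seed as in [comparison_spec()].
#' @return tibble as [run_comparison()], with `comparison` labels
#'   `"t2vst1"` built from the hour values (e.g. `"24vs6"`), in time order.
#' @export
timecourse_comparisons <- function(dataset, condition = NULL,
                                   test = "wilcoxon_rank_sum",
                                   quantities = c("abundance", "fractional",
                                                  "isotopologue"),
                                   correction = "BH", alpha = 0.05,
                                   n_permutations = 10000, seed = 123) {
  stopifnot(inherits(dataset, "TracerDataset"))
  sheet <- dataset$sample_sheet
  if (!is.null(condition)) sheet <- sheet[sheet$condition %in% condition, ]
  hours <- sort(unique(sheet$timepoint_hours))
  if (length(hours) < 2) {
    stop("time-course analysis needs at least 2 time points", call. = FALSE)
  }
  tests <- if (is.list(test)) {
    modifyList(list(abundance = "wilcoxon_rank_sum",
                    fractional = "wilcoxon_rank_sum",
                    isotopologue = "wilcoxon_rank_sum"), test)
  } else {
    assert_known_test(test)
    list(abundance = test, fractional = test, isotopologue = test)
  }
  fmt_h <- function(h) format(h, trim = TRUE, drop0trailing = TRUE)
  fams <- lapply(seq_len(length(hours) - 1), function(i) {
    label <- paste0(fmt_h(hours[i + 1]), "vs", fmt_h(hours[i]))
    spec <- comparison_spec(
      kind = "pairwise_condition",
      groups = list(list(condition = condition, timepoint = hours[i + 1]),
                    list(condition = condition, timepoint = hours[i])),
      name = label, tests = tests, correction = correction, alpha = alpha,
      n_permutations = n_permutations, seed = seed)
    run_comparison(dataset, spec, quantities = quantities)
  })
  out <- dplyr::bind_rows(fams)
  attr(out, "comparisons") <- vapply(seq_len(length(hours) - 1), function(i)
    paste0(fmt_h(hours[i + 1]), "vs", fmt_h(hours[i])), "")
  out
}

#' Flag time-responsive features
#'
#' A feature is time-responsive when it shows a significant difference in
#' at least one consecutive time-point comparison.
#'
#' @param results output of [timecourse_comparisons()].
#' @return tibble with `feature_id`, `quantity`, `n_significant`,
#'   `time_responsive`.
#' @export
time_responsive_features <- function(results) {
  results |>
    dplyr::group_by(.data$feature_id, .data$quantity) |>
    dplyr::summarise(n_significant = sum(.data$significant, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(time_responsive = .data$n_significant >= 1)
}
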