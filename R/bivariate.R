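#' Mean MDV profile of each metabolite within a sample group
#'
#' Profiles are group means of the per-sample isotopologue proportions
#' (condition-level MDVs), one vector of length n + 1 per metabolite.
#'
#' @param dataset a `TracerDataset` with isotopologue proportions.
#' @param selector group selector as in [resolve_samples()].
#' @return named list of numeric profiles (names = metabolites; element
#'   names `m+0..m+n`).
#' @export
mdv_profile_means <- function(dataset, selector) {
  stopifnot(inherits(dataset, "TracerDataset"))
  tbl <- dataset$isotopologue_prop
  if (is.null(tbl)) stop("dataset has no isotopologue proportions", call. = FALSE)
  samples <- intersect(resolve_samples(dataset$sample_sheet, selector),
                       colnames(tbl$values))
  if (!length(samples)) {
    stop(sprintf("selector %s resolves to zero samples", group_label(selector)),
         call. = FALSE)
  }
  sub <- tbl$values[, samples, drop = FALSE]
  means <- rowMeans(sub, na.rm = FALSE)
  split_means <- split(stats::setNames(means, paste0("m+", tbl$iso_index)),
                       tbl$metabolite)
  lapply(split_means, function(v) v[order(as.integer(sub("m\\+", "", names(v))))])
}

#' Spearman correlation of two MDV profiles
#'
#' Rank correlation (midranks for ties) between two labeling profiles of
#' equal length; high rho indicates the two groups distribute label across
#' isotopologues in the same rank order. The p-value is exact (permutation
#' null, the `stats::cor.test` AS89 route) for profiles of up to 8
#' isotopologues without ties, and t-approximated otherwise. A profile with
#' constant values has undefined rank variance; rho is then reported
#' missing with a reason code.
#'
#' @param profile_a,profile_b numeric vectors of equal length >= 3.
#' @return list with `rho`, `p_value`, `n` (profile length), `reason`.
#' @export
#' @examples
#' mdv_correlation(c(0.5, 0.3, 0.2), c(0.45, 0.35, 0.2))
mdv_correlation <- function(profile_a, profile_b) {
  if (length(profile_a) != length(profile_b)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  n <- length(profile_a)
  if (n < 3) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "profile_too_short"))
  }
  if (anyNA(profile_a) || anyNA(profile_b)) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "missing_values"))
  }
  if (stats::var(profile_a) == 0 || stats::var(profile_b) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                reason = "constant_profile"))
  }
  ties <- anyDuplicated(profile_a) || anyDuplicated(profile_b)
  ct <- suppressWarnings(cor.test(profile_a, profile_b, method = "spearman",
                                  exact = n <= 8 && !ties))
  list(rho = unname(ct$estimate), p_value = min(max(ct$p.value, 0), 1),
       n = n, reason = NA_character_)
}

#' Compare whole MDV profiles between two groups, metabolite by metabolite
#'
#' Bivariate analysis: for every metabolite with at least 3 isotopologues
#' (n >= 2; shorter profiles make rank correlation degenerate and are
#' excluded with a logged reason), correlates the group-mean MDV of group A
#' with that of group B by Spearman's test and adjusts p-values across
#' metabolites.
#'
#' @param dataset a `TracerDataset`.
#' @param group_a,group_b selectors as in [resolve_samples()].
#' @param correction FDR method.
#' @param alpha significance level on adjusted p-values.
#' @param name comparison label (default built from the selectors).
#' @return tibble with `metabolite`, `comparison`, `n_isotopologues`,
#'   `rho`, `p_raw`, `p_adj`, `significant`, `reason`.
#' @export
mdv_compare <- function(dataset, group_a, group_b, correction = "BH",
                        alpha = 0.05, name = NULL) {
  prof_a <- mdv_profile_means(dataset, group_a)
  prof_b <- mdv_profile_means(dataset, group_b)
  mets <- intersect(names(prof_a), names(prof_b))
  if (is.null(name)) {
    name <- paste(group_label(group_a), group_label(group_b), sep = "_vs_")
  }
  rows <- lapply(mets, function(met) {
    pa <- prof_a[[met]]; pb <- prof_b[[met]]
    if (length(pa) < 3) {
      res <- list(rho = NA_real_, p_value = NA_real_, n = length(pa),
                  reason = "fewer_than_3_isotopologues")
    } else {
      res <- mdv_correlation(pa, pb)
    }
    tibble::tibble(metabolite = met, comparison = name,
                   n_isotopologues = length(pa), rho = res$rho,
                   p_raw = res$p_value, reason = res$reason)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- adjust_pvalues(out$p_raw, correction)
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out[order(out$metabolite), ]
}

#' MDV profile comparison across consecutive time points
#'
#' Runs [mdv_compare()] for every consecutive pair t_{i+1} versus t_i of
#' the dataset's time course.
#'
#' @param dataset a `TracerDataset`.
#' @param condition optional condition restriction.
#' @param correction,alpha as in [mdv_compare()].
#' @return tibble of per-(comparison, metabolite) correlations.
#' @export
mdv_timecourse <- function(dataset, condition = NULL, correction = "BH",
                           alpha = 0.05) {
  sheet <- dataset$sample_sheet
  if (!is.null(condition)) sheet <- sheet[sheet$condition %in% condition, ]
  hours <- sort(unique(sheet$timepoint_hours))
  if (length(hours) < 2) {
    stop("time-course analysis needs at least 2 time points", call. = FALSE)
  }
  fmt_h <- function(h) format(h, trim = TRUE, drop0trailing = TRUE)
  dplyr::bind_rows(lapply(seq_len(length(hours) - 1), function(i) {
    mdv_compare(dataset,
                list(condition = condition, timepoint = hours[i + 1]),
                list(condition = condition, timepoint = hours[i]),
                correction = correction, alpha = alpha,
                name = paste0(fmt_h(hours[i + 1]), "vs", fmt_h(hours[i])))
  }))
}
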