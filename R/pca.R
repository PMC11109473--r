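#' PCA overview of samples
#'
#' Principal component analysis of a per-metabolite table (total abundances
#' or fractional contributions), samples as observations. Zero-variance
#' features are dropped (reported in the result). Components are made
#' deterministic up to data by fixing signs so that the largest-magnitude
#' loading of each component is positive.
#'
#' Default scaling is chosen by quantity: unit variance for abundances
#' (metabolite scales span orders of magnitude), none for fractional
#' contributions (already bounded in \[0, 1\]). An optional
#' `log10(x + offset)` transform for abundances uses half the minimum
#' positive value as offset.
#'
#' @param table a [metabolite_table()].
#' @param scaling `"auto"`, `"none"` or `"unit_variance"`.
#' @param n_components number of components to keep; clipped with a warning
#'   to `min(n_samples - 1, n_features)`.
#' @param log_transform log10-transform values before PCA (abundances).
#' @return a `PCAResult`: list with `scores` (sample x component),
#'   `loadings` (feature x component), `explained_variance_ratio` (over the
#'   full rank, so the kept components sum to <= 1), `dropped_features`,
#'   `scaling`, `center`, `scale`, `offset`.
#' @export
pca_overview <- function(table, scaling = c("auto", "none", "unit_variance"),
                         n_components = NULL, log_transform = FALSE) {
  stopifnot(inherits(table, "MetaboliteTable"))
  scaling <- match.arg(scaling)
  if (scaling == "auto") {
    scaling <- if (table$quantity == "total_abundance") "unit_variance" else "none"
  }
  x <- t(table$values) # samples x features
  if (nrow(x) < 3) stop("PCA needs at least 3 samples", call. = FALSE)
  keep <- colSums(is.na(x)) == 0
  x <- x[, keep, drop = FALSE]
  offset <- NA_real_
  if (log_transform) {
    pos <- x[x > 0]
    offset <- if (length(pos)) min(pos) / 2 else 1
    x <- log10(x + offset)
  }
  vars <- apply(x, 2, var)
  dropped <- colnames(x)[vars == 0]
  x <- x[, vars > 0, drop = FALSE]
  if (!ncol(x)) stop("no feature with non-zero variance", call. = FALSE)
  full_rank <- min(nrow(x) - 1, ncol(x))
  if (is.null(n_components)) n_components <- full_rank
  if (n_components > full_rank) {
    warning(sprintf("n_components clipped from %d to %d (rank limit)",
                    n_components, full_rank))
    n_components <- full_rank
  }
  fit <- prcomp(x, center = TRUE, scale. = (scaling == "unit_variance"))
  evr <- fit$sdev^2 / sum(fit$sdev^2)
  k <- seq_len(n_components)
  scores <- fit$x[, k, drop = FALSE]
  loadings <- fit$rotation[, k, drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in k) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_ratio = evr[k],
                 explained_variance_ratio_full = evr,
                 dropped_features = dropped, scaling = scaling,
                 center = fit$center,
                 scale = if (scaling == "unit_variance") fit$scale else NULL,
                 offset = offset),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d samples x %d components; variance explained: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}
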