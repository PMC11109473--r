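# Every figure returns its machine-readable twin table alongside the plot;
# tests and downstream exports assert on the tables, never on pixels.

summarise_groups <- function(values, sheet, groups) {
  rows <- lapply(groups, function(g) {
    samples <- intersect(resolve_samples(sheet, g), colnames(values))
    if (!length(samples)) return(NULL)
    sub <- values[, samples, drop = FALSE]
    tibble::tibble(feature_id = rownames(values),
                   group = group_label(g),
                   mean = unname(apply(sub, 1, mean, na.rm = TRUE)),
                   sd = unname(apply(sub, 1, sd, na.rm = TRUE)),
                   n = unname(apply(sub, 1, function(v) sum(!is.na(v)))))
  })
  skipped <- vapply(rows, is.null, TRUE)
  if (any(skipped)) {
    warning(sprintf("skipped empty groups: %s",
                    paste(vapply(groups[skipped], group_label, ""),
                          collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

replicate_points <- function(values, sheet, groups) {
  dplyr::bind_rows(lapply(groups, function(g) {
    samples <- intersect(resolve_samples(sheet, g), colnames(values))
    if (!length(samples)) return(NULL)
    sub <- values[, samples, drop = FALSE]
    tibble::tibble(feature_id = rep(rownames(sub), times = ncol(sub)),
                   group = group_label(g),
                   sample_id = rep(colnames(sub), each = nrow(sub)),
                   value = as.vector(sub))
  }))
}

# stable color key for isotopologues across every figure of a run
#' Stable isotopologue color key
#' @param max_index largest isotopologue index to map (m+0 .. m+max).
#' @return named character vector of hex colors, names `"m+0"`, ...
#' @export
isotopologue_palette <- function(max_index) {
  ramp <- grDevices::colorRampPalette(
    c("#DDDDDD", "#74ADD1", "#4575B4", "#FDAE61", "#D73027", "#7F0000"))
  # anchored at 13 levels (up to 12 carbons) so m+i keeps its color across
  # figures regardless of each figure's own largest index
  n_anchor <- max(max_index + 1L, 13L)
  stats::setNames(ramp(n_anchor)[seq_len(max_index + 1L)],
                  paste0("m+", 0:max_index))
}

#' Comparative abundance barplots
#'
#' Bar = group mean, error bar = standard deviation, individual replicate
#' points overlaid; the per-group replicate count is carried in the values
#' table (`n`) so missing replicates stay visible.
#'
#' @param table a [metabolite_table()].
#' @param sheet a [sample_sheet()].
#' @param groups list of group selectors ([resolve_samples()]).
#' @param metabolites optional subset of metabolites to show.
#' @return list with `plot` (ggplot) and `data` (tibble `feature_id`,
#'   `group`, `mean`, `sd`, `n`) and `points` (replicate values).
#' @export
abundance_bars <- function(table, sheet, groups, metabolites = NULL) {
  stopifnot(inherits(table, "MetaboliteTable"))
  values <- table$values
  if (!is.null(metabolites)) values <- values[metabolites, , drop = FALSE]
  data <- summarise_groups(values, sheet, groups)
  points <- replicate_points(values, sheet, groups)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$group, y = .data$mean,
                                          fill = .data$group)) +
    ggplot2::geom_col(width = 0.7, color = "grey25") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::geom_jitter(data = points,
                         ggplot2::aes(x = .data$group, y = .data$value),
                         inherit.aes = FALSE, width = 0.08, size = 1.2) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = NULL, y = table$quantity) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  list(plot = p, data = data, points = points)
}

#' Stacked isotopologue contribution bars
#'
#' Per group, mean isotopologue proportions stacked from m+0 (bottom) to
#' m+n (top); complete stacks have unit height up to the normalization
#' tolerance. Shares the run-wide isotopologue color key.
#'
#' @param table an [isotopologue_table()] in proportion mode.
#' @param sheet a [sample_sheet()].
#' @param groups list of group selectors.
#' @param metabolites optional metabolite subset.
#' @return list with `plot` and `data` (tibble `metabolite`, `iso_index`,
#'   `group`, `mean`, `sd`, `n`).
#' @export
isotopologue_stacked_bars <- function(table, sheet, groups,
                                      metabolites = NULL) {
  stopifnot(inherits(table, "IsotopologueTable"))
  if (table$mode != "proportion") {
    stop("stacked bars show proportions; convert absolute values first",
         call. = FALSE)
  }
  keep <- if (is.null(metabolites)) rep(TRUE, nrow(table$values)) else
    table$metabolite %in% metabolites
  values <- table$values[keep, , drop = FALSE]
  data <- summarise_groups(values, sheet, groups)
  parsed <- parse_isotopologue_ids(data$feature_id)
  data$metabolite <- parsed$metabolite
  data$iso_index <- parsed$iso_index
  data$isotopologue <- paste0("m+", data$iso_index)
  data <- data[order(data$metabolite, data$group, data$iso_index),
               c("metabolite", "iso_index", "isotopologue", "group",
                 "mean", "sd", "n")]
  pal <- isotopologue_palette(max(data$iso_index))
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$group, y = .data$mean,
                                    fill = .data$isotopologue)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE),
                      width = 0.7, color = "grey40", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = pal, name = "Isotopologue") +
    ggplot2::facet_wrap(~metabolite) +
    ggplot2::labs(x = NULL, y = "isotopologue proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
  list(plot = p, data = tibble::as_tibble(data))
}

#' Time-course curves of one quantity type
#'
#' Group mean with a +/- SD ribbon against time in hours (numeric spacing,
#' not ordinal), one panel per metabolite (per isotopologue feature for
#' proportion data).
#'
#' @param dataset a `TracerDataset`.
#' @param quantity `"abundance"`, `"fractional"` or `"isotopologue"`.
#' @param condition optional condition restriction.
#' @param metabolites optional metabolite subset.
#' @return list with `plot` and `data` (tibble `feature_id`, `hours`,
#'   `mean`, `sd`, `n`).
#' @export
timecourse_curves <- function(dataset,
                              quantity = c("abundance", "fractional",
                                           "isotopologue"),
                              condition = NULL, metabolites = NULL) {
  quantity <- match.arg(quantity)
  mats <- dataset_quantity_matrices(dataset, quantity)
  if (!length(mats)) stop("quantity not present in dataset", call. = FALSE)
  values <- mats[[1]]
  sheet <- dataset$sample_sheet
  if (!is.null(condition)) sheet <- sheet[sheet$condition %in% condition, ]
  hours <- sort(unique(sheet$timepoint_hours))
  if (length(hours) < 2) stop("need at least 2 time points", call. = FALSE)
  if (!is.null(metabolites)) {
    keep <- if (quantity == "isotopologue") {
      parse_isotopologue_ids(rownames(values))$metabolite %in% metabolites
    } else rownames(values) %in% metabolites
    values <- values[keep, , drop = FALSE]
  }
  groups <- lapply(hours, function(h) list(condition = condition,
                                           timepoint = h))
  data <- summarise_groups(values, sheet, groups)
  data$hours <- as.numeric(sub("^.*T", "", data$group))
  data <- data[, c("feature_id", "hours", "mean", "sd", "n")]
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$hours, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         fill = "grey80") +
    ggplot2::geom_line(color = "#4575B4") +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(~feature_id, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = quantity) +
    ggplot2::theme_minimal()
  list(plot = p, data = tibble::as_tibble(data))
}

#' PCA score plot
#'
#' @param pca a [pca_overview()] result.
#' @param sheet a [sample_sheet()].
#' @param components pair of component indices to show.
#' @return list with `plot` and `data` (scores joined with sample
#'   metadata).
#' @export
pca_plot <- function(pca, sheet, components = c(1, 2)) {
  stopifnot(inherits(pca, "PCAResult"))
  k <- components
  data <- tibble::tibble(sample_id = rownames(pca$scores),
                         x = pca$scores[, k[1]], y = pca$scores[, k[2]])
  data <- dplyr::left_join(data, tibble::as_tibble(sheet), by = "sample_id")
  lab <- function(i) sprintf("PC%d (%.1f%%)", i,
                             100 * pca$explained_variance_ratio[i])
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    color = .data$condition,
                                    shape = .data$timepoint_name)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = lab(k[1]), y = lab(k[2])) +
    ggplot2::theme_minimal()
  list(plot = p, data = data)
}

#' Save a figure as SVG and/or PNG
#'
#' Deterministic rendering is favoured: fixed device sizes and no
#' timestamp-bearing metadata in the PNG. SVG output requires cairo
#' support; when unavailable the format is skipped with a message.
#'
#' @param plot a ggplot object.
#' @param path_base output path without extension.
#' @param formats subset of `c("svg", "png")`.
#' @param width,height inches.
#' @param dpi PNG resolution.
#' @return character vector of files written, invisibly.
#' @export
save_figure <- function(plot, path_base, formats = c("svg", "png"),
                        width = 7, height = 5, dpi = 150) {
  written <- character()
  if ("svg" %in% formats) {
    if (capabilities("cairo")) {
      f <- paste0(path_base, ".svg")
      grDevices::svg(f, width = width, height = height)
      print(plot); grDevices::dev.off()
      written <- c(written, f)
    } else {
      message("cairo unavailable; skipping SVG for ", path_base)
    }
  }
  if ("png" %in% formats) {
    f <- paste0(path_base, ".png")
    grDevices::png(f, width = width * dpi, height = height * dpi, res = dpi)
    print(plot); grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}
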