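#' Pathway definition
#'
#' @param pathway_id pathway label.
#' @param metabolites character vector of member metabolite ids.
#' @param genes character vector of member gene symbols.
#' @return a `PathwayDefinition` list. At least one of the two member lists
#'   must be non-empty; ids must be unique within each list.
#' @export
pathway_definition <- function(pathway_id, metabolites = character(),
                               genes = character()) {
  metabolites <- as.character(metabolites); genes <- as.character(genes)
  if (!length(metabolites) && !length(genes)) {
    stop("a pathway needs at least one metabolite or gene member", call. = FALSE)
  }
  if (anyDuplicated(metabolites) || anyDuplicated(genes)) {
    stop("duplicated member ids within a pathway", call. = FALSE)
  }
  structure(list(pathway_id = pathway_id, metabolites = metabolites,
                 genes = genes),
            class = "PathwayDefinition")
}

#' Read pathway definitions from a tab-delimited file
#'
#' Columns: `pathway_id`, `member_type` (`metabolite` or `gene`),
#' `member_id`.
#'
#' @param path file path.
#' @return named list of [pathway_definition()] objects.
#' @export
read_pathways <- function(path) {
  df <- read_measurement_frame(path)
  required <- c("pathway_id", "member_type", "member_id")
  if (!all(required %in% names(df))) {
    abort_aggregate(setdiff(required, names(df)), "pathway file missing columns")
  }
  bad <- setdiff(unique(df$member_type), c("metabolite", "gene"))
  if (length(bad)) abort_aggregate(bad, "unknown member_type values")
  out <- lapply(split(df, df$pathway_id), function(d) {
    pathway_definition(d$pathway_id[1],
                       metabolites = d$member_id[d$member_type == "metabolite"],
                       genes = d$member_id[d$member_type == "gene"])
  })
  out
}

#' Validate a differential-gene-expression table
#'
#' The DEG table is consumed from an upstream transcriptomics analysis
#' (never computed here): one row per gene with a signed log2 fold change
#' and an adjusted p-value.
#'
#' @param df data frame with columns `gene`, `effect`, `p_adj`.
#' @return a validated tibble of class `DEGTable`.
#' @export
deg_table <- function(df) {
  required <- c("gene", "effect", "p_adj")
  if (!all(required %in% names(df))) {
    abort_aggregate(setdiff(required, names(df)), "DEG table missing columns")
  }
  df <- tibble::as_tibble(df[required])
  if (anyDuplicated(df$gene)) {
    abort_aggregate(unique(df$gene[duplicated(df$gene)]), "duplicated genes")
  }
  ok <- !is.na(df$p_adj)
  if (any(df$p_adj[ok] <= 0 | df$p_adj[ok] > 1)) {
    stop("DEG adjusted p-values must lie in (0, 1]", call. = FALSE)
  }
  class(df) <- c("DEGTable", class(df))
  df
}

#' Build a pathway metabologram
#'
#' Juxtaposes, for one biological comparison, the differential values of a
#' pathway's metabolites (inner ring) and genes (outer ring), each segment
#' carrying a signed effect and a significance flag. Members absent from
#' the results are included as neutral (value 0, flagged not measured), so
#' the pathway's full composition stays visible. The color domain is the
#' symmetric interval `[-M, M]` with `M` the largest absolute effect over
#' both omics in this pathway; in addition each omics side is normalized to
#' `[-1, 1]` on its own per-pathway scale (`value_scaled`) so one omics'
#' dynamic range cannot swamp the other.
#'
#' @param pathway a [pathway_definition()].
#' @param metabolite_results tibble with columns `feature_id`, `effect`,
#'   `p_adj` — one quantity type of a [run_comparison()] result for the
#'   same comparison the DEG table comes from (whether the metabolite side
#'   shows abundance or enrichment effects is the caller's choice).
#' @param deg a [deg_table()].
#' @param alpha significance level for the segment flags.
#' @return a `Metabologram`: list with `pathway_id`, `segments` (tibble
#'   `ring`, `id`, `value`, `value_scaled`, `significant`, `measured`,
#'   ordered alphabetically within each ring) and `value_domain`.
#' @export
build_metabologram <- function(pathway, metabolite_results, deg,
                               alpha = 0.05) {
  stopifnot(inherits(pathway, "PathwayDefinition"))
  lookup <- function(ids, tbl, id_col) {
    if (!length(ids)) {
      return(tibble::tibble(id = character(), value = numeric(),
                            significant = logical(), measured = logical()))
    }
    ids <- sort(ids)
    i <- match(ids, tbl[[id_col]])
    value <- ifelse(is.na(i), 0, tbl$effect[i])
    value[is.na(value)] <- 0
    padj <- tbl$p_adj[i]
    tibble::tibble(id = ids, value = value,
                   significant = !is.na(i) & !is.na(padj) & padj <= alpha,
                   measured = !is.na(i))
  }
  met <- lookup(pathway$metabolites, metabolite_results, "feature_id")
  gen <- lookup(pathway$genes, deg, "gene")
  if (!nrow(met) || !nrow(gen)) {
    warning(sprintf("pathway %s has members from only one omics; metabologram emitted with the present side",
                    pathway$pathway_id))
  }
  scale_side <- function(d) {
    m <- if (nrow(d)) max(abs(d$value)) else 0
    d$value_scaled <- if (m > 0) d$value / m else rep(0, nrow(d))
    d
  }
  met <- scale_side(met); gen <- scale_side(gen)
  segments <- dplyr::bind_rows(
    if (nrow(met)) dplyr::mutate(met, ring = "metabolite") else NULL,
    if (nrow(gen)) dplyr::mutate(gen, ring = "gene") else NULL)
  segments <- segments[, c("ring", "id", "value", "value_scaled",
                           "significant", "measured")]
  m_all <- max(abs(segments$value), 0)
  structure(list(pathway_id = pathway$pathway_id, segments = segments,
                 value_domain = c(-m_all, m_all), alpha = alpha),
            class = "Metabologram")
}

#' @export
print.Metabologram <- function(x, ...) {
  cat(sprintf("Metabologram [%s]: %d metabolite + %d gene segments, value domain [%.3g, %.3g]\n",
              x$pathway_id, sum(x$segments$ring == "metabolite"),
              sum(x$segments$ring == "gene"), x$value_domain[1],
              x$value_domain[2]))
  invisible(x)
}

#' Diverging color assignment for metabologram segments
#'
#' Maps each segment's scaled value in `[-1, 1]` to a symmetric diverging
#' palette (blue = decreased, white = 0, red = increased). The mapping is
#' odd-symmetric: negating every effect mirrors the palette index about
#' the midpoint.
#'
#' @param mg a [build_metabologram()] result.
#' @param levels palette resolution per half (default 100).
#' @return the segment tibble with `palette_index` (integer in
#'   `[-levels, levels]`) and `color` (hex) columns added.
#' @export
metabologram_colors <- function(mg, levels = 100) {
  stopifnot(inherits(mg, "Metabologram"))
  pal <- grDevices::colorRampPalette(c("#2166AC", "#FFFFFF", "#B2182B"))(2 * levels + 1)
  seg <- mg$segments
  seg$palette_index <- as.integer(round(seg$value_scaled * levels))
  seg$color <- pal[seg$palette_index + levels + 1L]
  seg
}

#' Plot a metabologram
#'
#' Donut rendering: metabolites inner ring, genes outer ring, alphabetical
#' within ring; non-significant segments are muted (reduced alpha), not
#' measured segments are hollow.
#'
#' @param mg a [build_metabologram()] result.
#' @return a ggplot object.
#' @export
metabologram_plot <- function(mg) {
  seg <- metabologram_colors(mg)
  seg <- dplyr::group_by(seg, .data$ring)
  seg <- dplyr::mutate(seg,
                       k = dplyr::row_number(),
                       xmin = (.data$k - 1) / dplyr::n(),
                       xmax = .data$k / dplyr::n())
  seg <- dplyr::ungroup(seg)
  seg$ymin <- ifelse(seg$ring == "metabolite", 0.4, 1.05)
  seg$ymax <- ifelse(seg$ring == "metabolite", 1.0, 1.65)
  seg$alpha <- ifelse(seg$significant, 1, 0.35)
  ggplot2::ggplot(seg) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = seg$color, alpha = seg$alpha,
                       color = "grey30", linewidth = 0.3) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$xmin + .data$xmax) / 2,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$id), size = 2.6) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1.8) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(mg$pathway_id)
}

#' Project differential results onto a pathway reaction network
#'
#' Annotates a user-supplied graph of metabolite and gene nodes with
#' differential status (DAM ovals, DEG rectangles by convention) and styles
#' an edge as a hypothesized slow flux when its product (target) metabolite
#' shows a significantly decreased fractional contribution while its total
#' abundance is non-decreasing — the signature of a metabolite that keeps
#' its pool while incorporating label more slowly, suggesting either a
#' slower flux through the producing reaction or dilution from an unlabeled
#' source. The styling is an interpretive aid, recorded as such in the
#' result metadata.
#'
#' @param edges data frame with columns `source`, `target`.
#' @param node_types data frame with columns `node_id`, `node_type`
#'   (`metabolite` or `gene`).
#' @param abundance_results,fractional_results tibbles with `feature_id`,
#'   `effect`, `p_adj` for the same comparison.
#' @param deg a [deg_table()].
#' @param alpha significance level.
#' @return a `PathwaySubnetwork`: list with `nodes` (tibble `node_id`,
#'   `node_type`, `shape`, `differential`), `edges` (tibble `source`,
#'   `target`, `style` in `solid`/`hypothesized-slow`), `graph` (igraph),
#'   `note`.
#' @export
project_subnetwork <- function(edges, node_types, abundance_results,
                               fractional_results, deg, alpha = 0.05) {
  edges <- tibble::as_tibble(edges)
  node_types <- tibble::as_tibble(node_types)
  stopifnot(all(c("source", "target") %in% names(edges)),
            all(c("node_id", "node_type") %in% names(node_types)))
  unknown <- setdiff(unique(c(edges$source, edges$target)),
                     node_types$node_id)
  if (length(unknown)) {
    abort_aggregate(unknown, "edge endpoints missing from the node table")
  }
  sig_dec <- function(tbl, id) {
    i <- match(id, tbl$feature_id)
    !is.na(i) & !is.na(tbl$p_adj[i]) & tbl$p_adj[i] <= alpha &
      tbl$effect[i] < 0
  }
  sig_any <- function(tbl, id, id_col = "feature_id") {
    i <- match(id, tbl[[id_col]])
    !is.na(i) & !is.na(tbl$p_adj[i]) & tbl$p_adj[i] <= alpha
  }
  abun_dec <- function(id) {
    i <- match(id, abundance_results$feature_id)
    !is.na(i) & !is.na(abundance_results$effect[i]) &
      abundance_results$effect[i] < 0
  }
  nodes <- node_types
  nodes$shape <- ifelse(nodes$node_type == "metabolite", "oval", "rectangle")
  nodes$differential <- ifelse(
    nodes$node_type == "metabolite",
    sig_any(abundance_results, nodes$node_id) |
      sig_any(fractional_results, nodes$node_id),
    sig_any(deg, nodes$node_id, "gene"))
  is_met <- nodes$node_type[match(edges$target, nodes$node_id)] == "metabolite"
  slow <- is_met & sig_dec(fractional_results, edges$target) &
    !abun_dec(edges$target)
  edges$style <- ifelse(slow, "hypothesized-slow", "solid")
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 note = "hypothesized-slow styling is an interpretive aid: significant enrichment decrease with non-decreasing abundance at the product metabolite"),
            class = "PathwaySubnetwork")
}
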