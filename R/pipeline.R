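# Full pipeline: preprocess -> differential / time-course / bivariate /
# PCA -> figures -> metabologram, driven by one validated configuration.
# Identical configuration + seed yields byte-identical result tables.

write_result_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  int <- vapply(df, is.integer, TRUE)
  for (col in names(df)[num & !int]) df[[col]] <- fmt_full(df[[col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

pipeline_log <- function(state, event, ...) {
  msg <- sprintf(event, ...)
  state$events[[length(state$events) + 1L]] <- list(event = msg)
  cat(msg, "\n", sep = "", file = state$human_log, append = TRUE)
  state
}

load_pipeline_dataset <- function(config) {
  ds <- config$dataset
  if (!is.null(ds$preset)) {
    return(generate_dataset(fixture_preset(ds$preset,
                                           seed = config$analysis$seed))$dataset)
  }
  iso <- if (!is.null(ds$isotopologues)) {
    read_isotopologue_table(ds$isotopologues, mode = ds$mode)
  }
  abun <- if (!is.null(ds$abundances)) {
    read_metabolite_table(ds$abundances, "total_abundance")
  }
  frac <- if (!is.null(ds$fractional)) {
    read_metabolite_table(ds$fractional, "fractional_contribution")
  }
  sheet <- read_sample_sheet(ds$sample_sheet)
  harmonize_inputs(isotopologues = iso, abundances = abun, fractional = frac,
                   sheet = sheet, tolerance = config$analysis$tolerance)
}

run_stage <- function(state, name, fn) {
  tryCatch(fn(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full configured analysis pipeline
#'
#' Loads (or simulates, when a preset is configured) the dataset, writes
#' the three derived measurement tables and the validation report, runs
#' every configured comparison, the time-course and bivariate analyses and
#' the PCA, renders figures, builds metabolograms when configured, and
#' writes a run manifest (configuration hash, seed, package version). The
#' output tree is `tables/`, `figures/`, `logs/` under `out_dir`.
#'
#' @param config path to a YAML configuration or an `isodiff_config`.
#' @param out_dir output directory (created; existing files overwritten).
#' @return (invisibly) list with `tables` (named list of tibbles written),
#'   `out_dir`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "isodiff_config")) config <- load_config(config)
  for (d in file.path(out_dir, c("tables", "figures", "logs"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  state <- list(events = list(),
                human_log = file.path(out_dir, "logs", "run.log"))
  cat("", file = state$human_log) # truncate
  an <- config$analysis
  tables <- list()

  dataset <- run_stage(state, "load", function() load_pipeline_dataset(config))
  state <- pipeline_log(state, "dataset loaded: %d samples",
                        nrow(dataset$sample_sheet))
  for (msg in dataset$log) state <- pipeline_log(state, "preprocess: %s", msg)

  # derived measurement tables + validation report
  for (nm in c("isotopologue_prop", "abundance", "fractional")) {
    if (!is.null(dataset[[nm]])) {
      write_measurement_table(dataset[[nm]],
                              file.path(out_dir, "tables",
                                        paste0(nm, ".tsv")))
    }
  }
  write_result_tsv(dataset$validation,
                   file.path(out_dir, "tables", "validation_report.tsv"))

  # pairwise / multigroup comparisons
  for (cmp in an$comparisons) {
    spec <- comparison_spec(kind = cmp$kind %||% "pairwise_condition",
                            groups = cmp$groups, name = cmp$name,
                            tests = an$tests, correction = an$fdr_method,
                            alpha = an$alpha,
                            n_permutations = an$n_permutations,
                            seed = an$seed)
    res <- run_stage(state, paste0("diff:", spec$name), function()
      run_comparison(dataset, spec))
    tables[[paste0("diff_", spec$name)]] <- res
    state <- pipeline_log(state, "comparison %s: %d features, %d significant",
                          spec$name, nrow(res), sum(res$significant))
  }

  # time-course + bivariate MDV analysis
  n_tp <- length(unique(dataset$sample_sheet$timepoint_hours))
  if (!is.null(an$timecourse) && n_tp >= 2) {
    tc <- an$timecourse
    res <- run_stage(state, "timecourse", function()
      timecourse_comparisons(dataset, condition = tc$condition,
                             test = tc$test %||% "wilcoxon_rank_sum",
                             correction = an$fdr_method, alpha = an$alpha,
                             n_permutations = an$n_permutations,
                             seed = an$seed))
    tables$timecourse <- res
    tables$time_responsive <- time_responsive_features(res)
    state <- pipeline_log(state, "timecourse: %d families",
                          length(attr(res, "comparisons")))
    biv <- run_stage(state, "bivariate", function()
      mdv_timecourse(dataset, condition = tc$condition,
                     correction = an$fdr_method, alpha = an$alpha))
    tables$mdv_timecourse <- biv
  } else if (!is.null(an$timecourse)) {
    state <- pipeline_log(state,
                          "timecourse skipped: only one time point present")
  }
  if (!is.null(an$bivariate)) {
    bv <- an$bivariate
    tables$mdv_comparison <- run_stage(state, "bivariate", function()
      mdv_compare(dataset, bv$groups[[1]], bv$groups[[2]],
                  correction = an$fdr_method, alpha = an$alpha))
  }

  # PCA overview
  pca_cfg <- an$pca
  pca_tbl <- switch(pca_cfg$quantity, abundance = dataset$abundance,
                    fractional = dataset$fractional)
  if (!is.null(pca_tbl) && ncol(pca_tbl$values) >= 3) {
    pca <- run_stage(state, "pca", function()
      pca_overview(pca_tbl, scaling = pca_cfg$scaling,
                   log_transform = isTRUE(pca_cfg$log_transform)))
    tables$pca_scores <- tibble::tibble(
      sample_id = rownames(pca$scores),
      tibble::as_tibble(pca$scores))
    tables$pca_variance <- tibble::tibble(
      component = seq_along(pca$explained_variance_ratio),
      explained_variance_ratio = pca$explained_variance_ratio)
    if (isTRUE(config$output$figures)) {
      fig <- pca_plot(pca, dataset$sample_sheet)
      save_figure(fig$plot, file.path(out_dir, "figures", "pca"),
                  formats = config$output$formats, dpi = config$output$dpi)
    }
  } else {
    state <- pipeline_log(state, "pca skipped: quantity unavailable or < 3 samples")
    pca <- NULL
  }

  # exploratory figures
  if (isTRUE(config$output$figures)) {
    sheet <- dataset$sample_sheet
    cond_groups <- lapply(unique(sheet$condition), function(cn)
      list(condition = cn))
    if (!is.null(dataset$abundance)) {
      fig <- abundance_bars(dataset$abundance, sheet, cond_groups)
      save_figure(fig$plot, file.path(out_dir, "figures", "abundance_bars"),
                  formats = config$output$formats, dpi = config$output$dpi)
      tables$abundance_bar_values <- fig$data
    }
    if (!is.null(dataset$isotopologue_prop)) {
      fig <- isotopologue_stacked_bars(dataset$isotopologue_prop, sheet,
                                       cond_groups)
      save_figure(fig$plot,
                  file.path(out_dir, "figures", "isotopologue_stacked_bars"),
                  formats = config$output$formats, dpi = config$output$dpi)
      tables$isotopologue_bar_values <- fig$data
    }
    if (n_tp >= 2 && !is.null(dataset$fractional)) {
      fig <- timecourse_curves(dataset, "fractional")
      save_figure(fig$plot,
                  file.path(out_dir, "figures", "fractional_timecourse"),
                  formats = config$output$formats, dpi = config$output$dpi)
      tables$fractional_curve_values <- fig$data
    }
  }

  # metabolograms
  mg_cfg <- config$metabologram
  if (!is.null(mg_cfg$pathways) && !is.null(mg_cfg$deg) &&
        length(an$comparisons)) {
    pathways <- read_pathways(mg_cfg$pathways)
    deg <- deg_table(read_measurement_frame(mg_cfg$deg))
    cmp_name <- mg_cfg$comparison %||% names(tables)[grep("^diff_", names(tables))][1]
    cmp_name <- sub("^diff_", "", cmp_name)
    res <- tables[[paste0("diff_", cmp_name)]]
    qty <- mg_cfg$metabolite_quantity
    met_res <- res[res$quantity == qty, ]
    seg_all <- list()
    for (pw in pathways) {
      mg <- build_metabologram(pw, met_res, deg, alpha = an$alpha)
      seg <- metabologram_colors(mg)
      seg$pathway_id <- pw$pathway_id
      seg_all[[pw$pathway_id]] <- seg
      if (isTRUE(config$output$figures)) {
        save_figure(metabologram_plot(mg),
                    file.path(out_dir, "figures",
                              paste0("metabologram_", pw$pathway_id)),
                    formats = config$output$formats, dpi = config$output$dpi)
      }
    }
    tables$metabologram_segments <- dplyr::bind_rows(seg_all)
    state <- pipeline_log(state, "metabolograms: %d pathways",
                          length(pathways))
  }

  for (nm in names(tables)) {
    write_result_tsv(tables[[nm]],
                     file.path(out_dir, "tables", paste0(nm, ".tsv")))
  }

  # manifest: configuration hash + seed + versions (no timestamps, so a
  # rerun with the same inputs produces an identical tree)
  cfg_file <- tempfile(fileext = ".yaml")
  dump_config(config, cfg_file)
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    seed = an$seed,
    package = "isodiff",
    package_version = as.character(utils::packageVersion("isodiff")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    tables = sort(names(tables)))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "logs", "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ev_con <- file(file.path(out_dir, "logs", "events.jsonl"), open = "wb")
  writeLines(vapply(state$events, function(e)
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE)), ""), ev_con)
  close(ev_con)
  invisible(list(tables = tables, out_dir = out_dir, manifest = manifest))
}
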