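# YAML run-configuration schema: every parameter the analyses take is
# named here once; load_config() validates against it, injects defaults,
# and reports all problems in one aggregated error.

config_defaults <- function() {
  list(
    dataset = list(isotopologues = NULL, mode = "absolute",
                   abundances = NULL, fractional = NULL,
                   sample_sheet = NULL, preset = NULL),
    analysis = list(
      comparisons = list(),
      timecourse = NULL,
      bivariate = NULL,
      tests = list(abundance = "permutation", fractional = "permutation",
                   isotopologue = "wilcoxon_rank_sum"),
      alpha = 0.05, fdr_method = "BH", n_permutations = 10000,
      tolerance = 0.02, seed = 123,
      pca = list(quantity = "abundance", scaling = "auto",
                 log_transform = FALSE)),
    metabologram = list(pathways = NULL, deg = NULL, graph_edges = NULL,
                        graph_nodes = NULL, metabolite_quantity = "abundance",
                        comparison = NULL),
    output = list(figures = TRUE, formats = c("svg", "png"), dpi = 150))
}

# recursively validate `cfg` against the default skeleton; unknown keys are
# rejected with their locations; list-of-entries keys are not descended.
check_unknown_keys <- function(cfg, defaults, path = "") {
  problems <- character()
  open_keys <- c("comparisons", "timecourse", "bivariate", "tests")
  for (key in names(cfg)) {
    here <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults)) {
      problems <- c(problems, sprintf("unknown key: %s", here))
    } else if (is.list(cfg[[key]]) && is.list(defaults[[key]]) &&
               !key %in% open_keys && length(names(defaults[[key]]))) {
      problems <- c(problems, check_unknown_keys(cfg[[key]], defaults[[key]],
                                                 here))
    }
  }
  problems
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (reporting their
#' locations), validates test and FDR method names and numeric parameters,
#' and injects documented defaults (`alpha` 0.05, `fdr_method` "BH",
#' `n_permutations` 10000, ...). All problems are reported at once.
#'
#' @param path YAML file path, or a list already in memory.
#' @return the validated configuration list (class `isodiff_config`).
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    yaml::read_yaml(path)
  }
  defaults <- config_defaults()
  problems <- check_unknown_keys(cfg, defaults)
  merged <- modifyList(defaults, cfg, keep.null = TRUE)
  # lists of unnamed entries are replaced wholesale (modifyList merges by
  # name and would drop them)
  if (!is.null(cfg$analysis$comparisons)) {
    merged$analysis$comparisons <- cfg$analysis$comparisons
  }

  tests <- merged$analysis$tests
  for (t in unlist(tests)) {
    if (!t %in% test_catalog()$name) {
      problems <- c(problems,
                    sprintf('unknown test "%s"; supported: %s', t,
                            paste(test_catalog()$name, collapse = ", ")))
    }
  }
  if (!tolower(merged$analysis$fdr_method) %in%
        tolower(names(fdr_method_registry()))) {
    problems <- c(problems,
                  sprintf('unknown fdr_method "%s"; supported: %s',
                          merged$analysis$fdr_method,
                          paste(unique(names(fdr_method_registry())),
                                collapse = ", ")))
  }
  a <- merged$analysis$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1) {
    problems <- c(problems, "analysis.alpha must lie in (0, 1)")
  }
  if (!is.numeric(merged$analysis$n_permutations) ||
        merged$analysis$n_permutations < 100) {
    problems <- c(problems, "analysis.n_permutations must be >= 100")
  }
  if (!is.null(merged$dataset$mode) &&
        !merged$dataset$mode %in% c("absolute", "proportion")) {
    problems <- c(problems, "dataset.mode must be absolute or proportion")
  }
  if (is.null(merged$dataset$preset) &&
        is.null(merged$dataset$isotopologues) &&
        is.null(merged$dataset$abundances) &&
        is.null(merged$dataset$fractional)) {
    problems <- c(problems, "dataset: no input tables and no preset named")
  }
  if (is.null(merged$dataset$preset) && is.null(merged$dataset$sample_sheet)) {
    problems <- c(problems, "dataset.sample_sheet is required with file inputs")
  }
  for (cmp in merged$analysis$comparisons) {
    if (is.null(cmp$groups) || length(cmp$groups) < 2) {
      problems <- c(problems,
                    sprintf("comparison %s: needs >= 2 groups",
                            cmp$name %||% "?"))
    }
  }
  if (length(problems)) abort_aggregate(problems, "invalid configuration")
  class(merged) <- c("isodiff_config", "list")
  merged
}

#' Write a configuration back to YAML
#'
#' A load -> dump -> load round trip is the identity on the validated
#' configuration.
#'
#' @param config an `isodiff_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
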