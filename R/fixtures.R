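# Deterministic synthetic tracer datasets emulating a 13C6-glucose SIRM
# design: per (condition, timepoint, replicate) sample, a total abundance is
# drawn log-normally around the condition mean and an MDV is drawn from a
# Dirichlet centered on the condition/timepoint mean MDV (replicate noise
# that stays on the simplex); absolute isotopologues are their product.
# Time courses start unlabeled (all mass at m+0, so enrichment is 0 at t=0)
# and relax exponentially toward a steady-state MDV, after which MDVs are
# time-invariant.

rdirichlet_one <- function(alpha) {
  # components with alpha == 0 are structural zeros (e.g. pre-labeling MDVs)
  g <- vapply(alpha, function(a) if (a > 0) rgamma(1, shape = a) else 0, 1)
  s <- sum(g)
  if (s == 0) c(1, rep(0, length(alpha) - 1)) else g / s
}

#' Specify a synthetic tracer dataset
#'
#' @param metabolites named integer vector: carbon count per metabolite id.
#' @param conditions character vector of condition names; the first is the
#'   reference, effects are injected into the others.
#' @param timepoints_h numeric hours (a single value means steady-state
#'   sampling at that time).
#' @param replicates replicates per (condition, timepoint).
#' @param effects tibble/data.frame with columns `metabolite`, `target`
#'   (`abundance` or `enrichment`), `direction` (`up`/`down`), `magnitude`
#'   — for abundance effects the shift of the log-mean in units of the
#'   log-scale SD (so magnitude 2 is a 2-sigma shift); for enrichment
#'   effects the mixing weight in `[0, 1]` pulling the steady MDV toward
#'   fully labeled (up) or unlabeled (down).
#' @param noise_cv coefficient of variation of replicate total abundances.
#' @param dirichlet_conc Dirichlet concentration (precision) of replicate
#'   MDV noise; larger = tighter replicates.
#' @param label_rate exponential labeling rate constant (1/h) used for
#'   time courses.
#' @param seed integer; generation is fully reproducible.
#' @return a `FixtureSpec` list.
#' @export
fixture_spec <- function(metabolites, conditions = "Control",
                         timepoints_h = 48, replicates = 3,
                         effects = NULL, noise_cv = 0.2,
                         dirichlet_conc = 150, label_rate = 0.25,
                         seed = 1) {
  stopifnot(is.numeric(metabolites), !is.null(names(metabolites)),
            all(metabolites >= 1), replicates >= 1, noise_cv > 0,
            dirichlet_conc > 0)
  if (is.null(effects)) {
    effects <- tibble::tibble(metabolite = character(), target = character(),
                              direction = character(), magnitude = numeric())
  }
  effects <- tibble::as_tibble(effects)
  if (nrow(effects)) {
    stopifnot(all(effects$magnitude >= 0),
              all(effects$target %in% c("abundance", "enrichment")),
              all(effects$direction %in% c("up", "down")))
    bad <- setdiff(effects$metabolite, names(metabolites))
    if (length(bad)) abort_aggregate(bad, "effects reference undeclared metabolites")
  }
  structure(list(metabolites = metabolites, conditions = conditions,
                 timepoints_h = sort(unique(timepoints_h)),
                 replicates = as.integer(replicates), effects = effects,
                 noise_cv = noise_cv, dirichlet_conc = dirichlet_conc,
                 label_rate = label_rate, seed = as.integer(seed)),
            class = "FixtureSpec")
}

#' Named fixture presets
#'
#' Two presets mirror the study designs the package is exercised on:
#' `"ldh_ko_48h"` — two conditions (Control vs a lactate-dehydrogenase
#' double-KO analog) in triplicate at 48 h, ten TCA-cycle/amino-acid
#' metabolites including 5-carbon alpha-ketoglutarate and glutamate
#' analogs, with an AKG abundance increase and AKG/glutamate enrichment
#' decreases injected; `"timecourse_p3"` — one condition sampled in
#' triplicate at 0, 1, 2, 4, 6 and 24 h of labeling.
#'
#' @param name preset name.
#' @param seed overrides the preset seed.
#' @return a [fixture_spec()].
#' @export
fixture_preset <- function(name = c("ldh_ko_48h", "timecourse_p3"),
                           seed = NULL) {
  name <- match.arg(name)
  mets <- c(Pyruvate = 3, Lactate = 3, Citrate = 6, AKG = 5, Succinate = 4,
            Fumarate = 4, Malate = 4, Aspartate = 4, Glutamate = 5,
            Glutamine = 5)
  spec <- switch(name,
    ldh_ko_48h = fixture_spec(
      metabolites = mets,
      conditions = c("Control", "LDHAB_KO"),
      timepoints_h = 48, replicates = 3,
      effects = tibble::tibble(
        metabolite = c("AKG", "Lactate", "Malate", "AKG", "Glutamate"),
        target = c("abundance", "abundance", "abundance",
                   "enrichment", "enrichment"),
        direction = c("up", "down", "up", "down", "down"),
        magnitude = c(2, 2, 2, 0.35, 0.35)),
      noise_cv = 0.2, dirichlet_conc = 150, seed = 20480),
    timecourse_p3 = fixture_spec(
      metabolites = mets,
      conditions = "Control",
      timepoints_h = c(0, 1, 2, 4, 6, 24), replicates = 3,
      effects = NULL, noise_cv = 0.2, dirichlet_conc = 150,
      label_rate = 0.25, seed = 20481))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  spec
}

#' Generate a synthetic tracer dataset with known ground truth
#'
#' Draws absolute isotopologue tables per sample (total abundance times
#' MDV), assembles them with [harmonize_inputs()] into all three quantity
#' types, and returns the ground-truth effect table alongside. Generation
#' is byte-deterministic for a fixed spec (including its seed) and leaves
#' the caller's RNG state untouched.
#'
#' @param spec a [fixture_spec()] or preset name.
#' @return list with `dataset` (a `TracerDataset`), `ground_truth` (the
#'   injected effects) and `spec`.
#' @export
#' @examples
#' sim <- generate_dataset(fixture_preset("ldh_ko_48h"))
#' sim$dataset
generate_dataset <- function(spec) {
  if (is.character(spec)) spec <- fixture_preset(spec)
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    mets <- names(spec$metabolites)
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    # per-metabolite baselines, drawn once
    base_meanlog <- stats::setNames(log(10^runif(length(mets), 5, 7)), mets)
    steady_mdv <- lapply(mets, function(met) {
      n <- spec$metabolites[[met]]
      rdirichlet_one(rep(2, n + 1))
    })
    names(steady_mdv) <- mets
    rate <- stats::setNames(spec$label_rate * runif(length(mets), 0.6, 1.4),
                            mets)

    eff_of <- function(met, target) {
      e <- spec$effects[spec$effects$metabolite == met &
                          spec$effects$target == target, ]
      if (!nrow(e)) return(0)
      sum(ifelse(e$direction == "up", 1, -1) * e$magnitude)
    }
    mean_mdv_at <- function(met, condition, t) {
      n <- spec$metabolites[[met]]
      lam <- if (length(spec$timepoints_h) == 1) 1 else
        1 - exp(-rate[[met]] * t)
      mdv <- (1 - lam) * c(1, rep(0, n)) + lam * steady_mdv[[met]]
      if (condition != spec$conditions[1]) {
        delta <- eff_of(met, "enrichment")
        if (delta > 0) {
          mdv <- (1 - min(delta, 1)) * mdv +
            min(delta, 1) * c(rep(0, n), 1)
        } else if (delta < 0) {
          mdv <- (1 - min(-delta, 1)) * mdv +
            min(-delta, 1) * c(1, rep(0, n))
        }
      }
      mdv
    }

    design <- expand.grid(replicate = seq_len(spec$replicates),
                          timepoint = spec$timepoints_h,
                          condition = spec$conditions,
                          stringsAsFactors = FALSE)
    fmt_h <- function(h) format(h, trim = TRUE, drop0trailing = TRUE)
    design$sample_id <- sprintf("%s_T%s_%d", design$condition,
                                fmt_h(design$timepoint), design$replicate)
    sheet <- sample_sheet(data.frame(
      sample_id = design$sample_id, condition = design$condition,
      timepoint_name = paste0("T", fmt_h(design$timepoint)),
      timepoint_hours = design$timepoint, replicate = design$replicate))

    feature_ids <- unlist(lapply(mets, function(met)
      paste0(met, "_m+", 0:spec$metabolites[[met]])))
    values <- matrix(NA_real_, nrow = length(feature_ids),
                     ncol = nrow(design),
                     dimnames = list(feature_ids, design$sample_id))
    for (s in seq_len(nrow(design))) {
      cond <- design$condition[s]; t <- design$timepoint[s]
      for (met in mets) {
        meanlog <- base_meanlog[[met]]
        if (cond != spec$conditions[1]) {
          meanlog <- meanlog + eff_of(met, "abundance") * sdlog
        }
        total <- rlnorm(1, meanlog = meanlog, sdlog = sdlog)
        mdv <- rdirichlet_one(spec$dirichlet_conc *
                                mean_mdv_at(met, cond, t))
        rows <- paste0(met, "_m+", 0:spec$metabolites[[met]])
        values[rows, s] <- total * mdv
      }
    }
    iso <- isotopologue_table(values, mode = "absolute",
                              carbon_count = spec$metabolites)
    dataset <- harmonize_inputs(isotopologues = iso, sheet = sheet)
    list(dataset = dataset, ground_truth = spec$effects, spec = spec)
  })
}

#' Generate a synthetic differential-gene-expression table
#'
#' Builds a DEG table with known ground truth for integration tests:
#' configured genes carry the configured log2 fold change (plus small
#' noise) and adjusted p-values below `alpha`; all other genes are
#' non-significant by construction (the generator's purpose is a known
#' truth assignment, not a realistic null calibration — documented as
#' synthetic).
#'
#' @param genes character vector of all gene symbols to emit.
#' @param effects named numeric vector: configured log2 fold changes for a
#'   subset of `genes`.
#' @param alpha significance level the flags are built against.
#' @param seed integer seed.
#' @return a [deg_table()] with an extra logical column `configured`.
#' @export
generate_deg_table <- function(genes, effects = numeric(), alpha = 0.05,
                               seed = 1) {
  stopifnot(all(names(effects) %in% genes))
  with_seed(seed, {
    configured <- genes %in% names(effects)
    effect <- rnorm(length(genes), mean = 0, sd = 0.1)
    effect[configured] <- effects[genes[configured]] +
      rnorm(sum(configured), 0, 0.05)
    p_adj <- runif(length(genes), min = max(alpha, 0.05) + 0.1, max = 1)
    p_adj[configured] <- runif(sum(configured), min = 1e-6,
                               max = alpha / 2)
    out <- deg_table(tibble::tibble(gene = genes, effect = effect,
                                    p_adj = p_adj))
    out$configured <- configured
    out
  })
}
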