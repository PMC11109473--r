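#' Total metabolite abundance from absolute isotopologues
#'
#' For each metabolite and sample, the total abundance is the sum of its
#' absolute isotopologue intensities, m = sum_j M_j. A missing isotopologue
#' value propagates to a missing total (no silent partial sums).
#'
#' @param table an [isotopologue_table()] in `absolute` mode.
#' @return a [metabolite_table()] with `quantity = "total_abundance"`.
#' @export
#' @examples
#' m <- matrix(c(10, 30, 60), ncol = 1,
#'             dimnames = list(c("pyr_m+0", "pyr_m+1", "pyr_m+2"), "s1"))
#' total_abundance(isotopologue_table(m, "absolute"))$values
total_abundance <- function(table) {
  stopifnot(inherits(table, "IsotopologueTable"))
  if (table$mode != "absolute") {
    stop("total abundances require absolute isotopologue values, not proportions",
         call. = FALSE)
  }
  sums <- rowsum(table$values, table$metabolite, na.rm = FALSE)
  sums <- sums[unique(table$metabolite), , drop = FALSE]
  metabolite_table(sums, quantity = "total_abundance")
}

#' Isotopologue proportions (mass distribution vector) from absolute values
#'
#' Normalizes each metabolite's isotopologue vector per sample to its sum:
#' c_i = M_i / sum_j M_j. Cells with zero total are undefined (0/0) and
#' recorded as missing rather than fabricated.
#'
#' @param table an [isotopologue_table()] in `absolute` mode.
#' @return an [isotopologue_table()] in `proportion` mode.
#' @export
isotopologue_proportions <- function(table) {
  stopifnot(inherits(table, "IsotopologueTable"))
  if (table$mode != "absolute") {
    stop("input is already in proportion mode", call. = FALSE)
  }
  sums <- rowsum(table$values, table$metabolite, na.rm = FALSE)
  denom <- sums[table$metabolite, , drop = FALSE]
  prop <- table$values / denom
  prop[!is.na(denom) & denom == 0] <- NA_real_
  isotopologue_table(prop, mode = "proportion",
                     carbon_count = table$carbon_count)
}

#' Fractional contribution (mean enrichment) from isotopologue proportions
#'
#' The fractional contribution of a metabolite with n carbons is the
#' carbon-weighted mean of its MDV, phi = sum_j (c_j * j) / n — 0 when all
#' mass is unlabeled (m+0), 1 when fully labeled (m+n). It proxies the speed
#' of label incorporation from the tracer.
#'
#' @param table an [isotopologue_table()] in `proportion` mode.
#' @return a [metabolite_table()] with `quantity = "fractional_contribution"`.
#' @export
#' @examples
#' m <- matrix(c(0.25, 0.5, 0.25), ncol = 1,
#'             dimnames = list(c("gly_m+0", "gly_m+1", "gly_m+2"), "s1"))
#' fractional_contribution(isotopologue_table(m, "proportion"))$values
fractional_contribution <- function(table) {
  stopifnot(inherits(table, "IsotopologueTable"))
  if (table$mode != "proportion") {
    stop("fractional contributions are computed from proportions; convert first",
         call. = FALSE)
  }
  if (any(table$carbon_count == 0)) {
    abort_aggregate(names(table$carbon_count)[table$carbon_count == 0],
                    "enrichment undefined for 0-carbon metabolites")
  }
  weighted <- table$values * table$iso_index
  phi <- rowsum(weighted, table$metabolite, na.rm = FALSE)
  phi <- phi[unique(table$metabolite), , drop = FALSE]
  phi <- phi / table$carbon_count[rownames(phi)]
  phi <- pmin(pmax(phi, 0), 1) # guard FP round-off at the boundaries
  metabolite_table(phi, quantity = "fractional_contribution")
}

#' Assemble a complete tracer dataset from raw inputs
#'
#' Aligns all tables to the sample sheet and derives any quantity type that
#' is missing but derivable from the isotopologue data: absolute
#' isotopologues yield proportions, total abundances and fractional
#' contributions; proportion-mode input yields fractional contributions only
#' (totals are then unavailable unless supplied). User-supplied tables take
#' precedence over derived ones; when both exist they are compared and
#' discrepancies beyond `1e-6` relative are logged.
#'
#' Proportion input whose per-(metabolite, sample) sums are ~100 is
#' auto-detected as percentages and rescaled by 1/100 (logged): both
#' conventions circulate in upstream correction tools.
#'
#' @param isotopologues an [isotopologue_table()] (either mode), or NULL.
#' @param abundances optional [metabolite_table()] (`total_abundance`).
#' @param fractional optional [metabolite_table()]
#'   (`fractional_contribution`).
#' @param sheet a [sample_sheet()].
#' @param tolerance normalization tolerance for validation (default 0.02).
#' @return a `TracerDataset`: list with elements `isotopologue_abs`,
#'   `isotopologue_prop`, `abundance`, `fractional` (each possibly NULL),
#'   `sample_sheet`, `validation` (violation tibble) and `log` (character).
#' @export
harmonize_inputs <- function(isotopologues = NULL, abundances = NULL,
                             fractional = NULL, sheet, tolerance = 0.02) {
  stopifnot(inherits(sheet, "SampleSheet"))
  if (is.null(isotopologues) && is.null(abundances) && is.null(fractional)) {
    stop("no measurement tables supplied", call. = FALSE)
  }
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  align <- function(values, what) {
    extra <- setdiff(colnames(values), sheet$sample_id)
    if (length(extra)) {
      abort_aggregate(extra, paste("samples in", what, "absent from the sample sheet"))
    }
    keep <- sheet$sample_id[sheet$sample_id %in% colnames(values)]
    if (length(keep) < nrow(sheet)) {
      note(sprintf("%s: %d sheet samples have no measurements",
                   what, nrow(sheet) - length(keep)))
    }
    values[, keep, drop = FALSE]
  }

  iso_abs <- iso_prop <- NULL
  if (!is.null(isotopologues)) {
    stopifnot(inherits(isotopologues, "IsotopologueTable"))
    vals <- align(isotopologues$values, "isotopologues")
    if (isotopologues$mode == "proportion") {
      sums <- rowsum(vals, isotopologues$metabolite, na.rm = FALSE)
      finite_sums <- sums[!is.na(sums)]
      if (length(finite_sums) && all(finite_sums >= 98 & finite_sums <= 102)) {
        vals <- vals / 100
        note("isotopologue proportions supplied as percentages; rescaled by 1/100")
      }
      iso_prop <- isotopologue_table(vals, "proportion",
                                     carbon_count = isotopologues$carbon_count)
    } else {
      iso_abs <- isotopologue_table(vals, "absolute",
                                    carbon_count = isotopologues$carbon_count)
      iso_prop <- isotopologue_proportions(iso_abs)
      note("derived isotopologue proportions from absolute values")
    }
  }

  validation <- if (!is.null(iso_abs)) {
    validate_isotopologue_table(iso_abs, tolerance)
  } else if (!is.null(iso_prop)) {
    validate_isotopologue_table(iso_prop, tolerance)
  } else {
    tibble::tibble(metabolite = character(), sample = character(),
                   rule = character(), detail = character())
  }

  compare_supplied <- function(supplied, derived, what) {
    common_r <- intersect(rownames(supplied$values), rownames(derived$values))
    common_c <- intersect(colnames(supplied$values), colnames(derived$values))
    if (!length(common_r) || !length(common_c)) return(invisible())
    d <- rel_diff(supplied$values[common_r, common_c, drop = FALSE],
                  derived$values[common_r, common_c, drop = FALSE])
    n_bad <- sum(d > 1e-6, na.rm = TRUE)
    if (n_bad > 0) {
      note(sprintf("%s: supplied table disagrees with values derived from isotopologues in %d cells (max rel. diff %.3g); supplied table retained",
                   what, n_bad, max(d, na.rm = TRUE)))
    }
  }

  abun <- NULL
  if (!is.null(abundances)) {
    stopifnot(inherits(abundances, "MetaboliteTable"),
              abundances$quantity == "total_abundance")
    abun <- metabolite_table(align(abundances$values, "abundances"),
                             "total_abundance")
    if (!is.null(iso_abs)) compare_supplied(abun, total_abundance(iso_abs),
                                            "total abundances")
  } else if (!is.null(iso_abs)) {
    abun <- total_abundance(iso_abs)
    note("derived total abundances from absolute isotopologues")
  } else if (!is.null(iso_prop)) {
    note("total abundances unavailable: proportion-mode input carries no scale")
  }

  frac <- NULL
  if (!is.null(fractional)) {
    stopifnot(inherits(fractional, "MetaboliteTable"),
              fractional$quantity == "fractional_contribution")
    frac <- metabolite_table(align(fractional$values, "fractional contributions"),
                             "fractional_contribution", tolerance = tolerance)
    if (!is.null(iso_prop)) {
      compare_supplied(frac, fractional_contribution(iso_prop),
                       "fractional contributions")
    }
  } else if (!is.null(iso_prop)) {
    frac <- fractional_contribution(iso_prop)
    note("derived fractional contributions from isotopologue proportions")
  }

  structure(list(isotopologue_abs = iso_abs,
                 isotopologue_prop = iso_prop,
                 abundance = abun,
                 fractional = frac,
                 sample_sheet = sheet,
                 validation = validation,
                 log = log),
            class = "TracerDataset")
}

#' @export
print.TracerDataset <- function(x, ...) {
  have <- c(`absolute isotopologues` = !is.null(x$isotopologue_abs),
            `isotopologue proportions` = !is.null(x$isotopologue_prop),
            `total abundances` = !is.null(x$abundance),
            `fractional contributions` = !is.null(x$fractional))
  cat(sprintf("TracerDataset: %d samples; tables: %s\n", nrow(x$sample_sheet),
              paste(names(have)[have], collapse = ", ")))
  if (nrow(x$validation)) {
    cat(sprintf("  %d validation violations\n", nrow(x$validation)))
  }
  invisible(x)
}
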