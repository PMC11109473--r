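#' Isotopologue measurement table
#'
#' Container for corrected isotopologue measurements: one row per
#' (metabolite, isotopologue index) pair, one column per sample. Rows are
#' identified by the `"metabolite_m+i"` convention (`i` = number of heavy
#' carbons, `0..n` for a metabolite with `n` carbons). Values are either
#' `absolute` intensities (the M0..Mn of a mass distribution vector before
#' normalization) or `proportion`s (isotopologue contributions c0..cn,
#' summing to 1 per metabolite and sample).
#'
#' @param values numeric matrix, rows = isotopologue features with rownames
#'   following `"metabolite_m+i"`, columns = samples (named).
#' @param mode `"absolute"` or `"proportion"`.
#' @param carbon_count optional named integer vector giving the carbon count
#'   `n` per metabolite. When omitted it is inferred as (number of
#'   isotopologue rows - 1); a supplied value that disagrees with the row
#'   structure is an error.
#' @return an object of class `IsotopologueTable` with elements `values`,
#'   `metabolite`, `iso_index`, `carbon_count`, `mode`.
#' @export
#' @examples
#' m <- matrix(c(10, 30, 60), ncol = 1,
#'             dimnames = list(c("pyr_m+0", "pyr_m+1", "pyr_m+2"), "s1"))
#' isotopologue_table(m, mode = "absolute")
isotopologue_table <- function(values, mode = c("absolute", "proportion"),
                               carbon_count = NULL) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("isotopologue values need rownames (feature ids) and colnames (sample ids)",
         call. = FALSE)
  }
  storage.mode(values) <- "double"
  parsed <- parse_isotopologue_ids(rownames(values))
  key <- paste0(parsed$metabolite, "_m+", parsed$iso_index)
  if (anyDuplicated(key)) {
    abort_aggregate(unique(key[duplicated(key)]),
                    "duplicated (metabolite, isotopologue) rows")
  }
  rownames(values) <- key
  n_inferred <- tapply(parsed$iso_index, parsed$metabolite, max)
  n_rows <- tapply(parsed$iso_index, parsed$metabolite, length)
  # carbon count: supplied wins only if consistent with the rows present
  if (is.null(carbon_count)) {
    carbon_count <- as.integer(n_inferred)
    names(carbon_count) <- names(n_inferred)
  } else {
    carbon_count <- carbon_count[names(n_inferred)]
    bad <- names(n_inferred)[is.na(carbon_count) |
                               carbon_count < n_inferred]
    if (length(bad)) {
      abort_aggregate(bad, "supplied carbon counts missing or below observed max isotopologue index")
    }
    mism <- names(n_inferred)[carbon_count != n_inferred &
                                n_rows == n_inferred + 1]
    if (length(mism)) {
      abort_aggregate(mism, "supplied carbon count disagrees with isotopologue rows")
    }
    carbon_count <- as.integer(carbon_count)
    names(carbon_count) <- names(n_inferred)
  }
  structure(list(values = values,
                 metabolite = parsed$metabolite,
                 iso_index = parsed$iso_index,
                 carbon_count = carbon_count,
                 mode = mode),
            class = "IsotopologueTable")
}

# Accepts "Met_m+3" ids; returns metabolite / integer index.
parse_isotopologue_ids <- function(ids) {
  ok <- grepl("_m\\+[0-9]+$", ids)
  if (!all(ok)) {
    abort_aggregate(ids[!ok], 'feature ids not matching the "metabolite_m+i" convention')
  }
  idx <- as.integer(sub("^.*_m\\+([0-9]+)$", "\\1", ids))
  met <- sub("_m\\+[0-9]+$", "", ids)
  list(metabolite = met, iso_index = idx)
}

#' @export
print.IsotopologueTable <- function(x, ...) {
  cat(sprintf("IsotopologueTable [%s]: %d metabolites, %d isotopologue rows, %d samples\n",
              x$mode, length(unique(x$metabolite)), nrow(x$values),
              ncol(x$values)))
  invisible(x)
}

#' Per-metabolite scalar measurement table
#'
#' One row per metabolite, one column per sample. `quantity` is either
#' `total_abundance` (sum of absolute isotopologue intensities, >= 0) or
#' `fractional_contribution` (carbon-weighted mean enrichment, in \[0, 1\]).
#'
#' @param values numeric matrix, rownames = metabolites, colnames = samples.
#' @param quantity `"total_abundance"` or `"fractional_contribution"`.
#' @param tolerance numeric slack on the \[0, 1\] bounds for fractional
#'   contributions.
#' @return an object of class `MetaboliteTable`.
#' @export
metabolite_table <- function(values,
                             quantity = c("total_abundance",
                                          "fractional_contribution"),
                             tolerance = 0.02) {
  quantity <- match.arg(quantity)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("metabolite values need rownames and colnames", call. = FALSE)
  }
  storage.mode(values) <- "double"
  if (anyDuplicated(rownames(values))) {
    abort_aggregate(unique(rownames(values)[duplicated(rownames(values))]),
                    "duplicated metabolite rows")
  }
  v <- values[!is.na(values)]
  if (quantity == "total_abundance" && any(v < 0)) {
    stop("total abundances must be non-negative", call. = FALSE)
  }
  if (quantity == "fractional_contribution" &&
      any(v < -tolerance | v > 1 + tolerance)) {
    stop("fractional contributions must lie in [0, 1] (within tolerance)",
         call. = FALSE)
  }
  structure(list(values = values, quantity = quantity),
            class = "MetaboliteTable")
}

#' @export
print.MetaboliteTable <- function(x, ...) {
  cat(sprintf("MetaboliteTable [%s]: %d metabolites, %d samples\n",
              x$quantity, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Sample metadata sheet
#'
#' Maps each sample to its condition, time point (ordered by a numeric hour
#' value) and replicate index — the experimental design against which
#' comparison groups are resolved.
#'
#' @param df data frame with columns `sample_id`, `condition`,
#'   `timepoint_name`, `timepoint_hours`, `replicate`.
#' @return a validated `SampleSheet` (a tibble subclass).
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "condition", "timepoint_name",
                "timepoint_hours", "replicate")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    abort_aggregate(missing_cols, "sample sheet missing columns")
  }
  df <- tibble::as_tibble(df[required])
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$timepoint_name <- as.character(df$timepoint_name)
  df$timepoint_hours <- as.numeric(df$timepoint_hours)
  df$replicate <- as.integer(df$replicate)
  problems <- character()
  if (anyDuplicated(df$sample_id)) {
    problems <- c(problems, paste("duplicated sample ids:",
                                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                                        collapse = ", ")))
  }
  if (anyNA(df$timepoint_hours)) {
    problems <- c(problems, "non-numeric timepoint_hours")
  }
  # one name per hour value and vice versa
  map <- unique(df[c("timepoint_name", "timepoint_hours")])
  if (anyDuplicated(map$timepoint_name) || anyDuplicated(map$timepoint_hours)) {
    problems <- c(problems, "timepoint_name / timepoint_hours mapping is not one-to-one")
  }
  if (length(problems)) abort_aggregate(problems, "invalid sample sheet")
  class(df) <- c("SampleSheet", class(df))
  df
}

#' Resolve the samples belonging to a (condition, timepoint) group
#'
#' @param sheet a [sample_sheet()].
#' @param selector list with optional elements `condition` and `timepoint`
#'   (a `timepoint_name`, or a numeric hour value).
#' @return character vector of sample ids (possibly empty).
#' @export
resolve_samples <- function(sheet, selector = list()) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(selector$condition)) {
    keep <- keep & sheet$condition %in% selector$condition
  }
  if (!is.null(selector$timepoint)) {
    tp <- selector$timepoint
    if (is.numeric(tp)) {
      keep <- keep & sheet$timepoint_hours %in% tp
    } else {
      keep <- keep & (sheet$timepoint_name %in% as.character(tp) |
                        sheet$timepoint_hours %in%
                          suppressWarnings(as.numeric(tp)))
    }
  }
  sheet$sample_id[keep]
}

group_label <- function(selector) {
  parts <- c(selector$condition,
             if (!is.null(selector$timepoint)) paste0("T", selector$timepoint))
  paste(parts, collapse = "-")
}

#' Validate an isotopologue table against the MDV invariants
#'
#' Checks, per metabolite and sample: contiguous isotopologue indices
#' `0..n`; non-negative values in absolute mode; in proportion mode each
#' value in `[0, 1 + tolerance]` and the per-(metabolite, sample) sum within
#' `1 +/- tolerance`. Cells containing missing values are not judged for
#' normalization (their sum is undefined).
#'
#' @param table an [isotopologue_table()].
#' @param tolerance normalization slack epsilon (default 0.02; upstream
#'   correction tools commonly leave percent-level residuals).
#' @return tibble of violations with columns `metabolite`, `sample`, `rule`,
#'   `detail`; zero rows when the table is valid. Validation never modifies
#'   its input.
#' @export
validate_isotopologue_table <- function(table, tolerance = 0.02) {
  stopifnot(inherits(table, "IsotopologueTable"))
  v <- list()
  add <- function(metabolite, sample, rule, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(metabolite = metabolite,
                                           sample = sample, rule = rule,
                                           detail = detail)
  }
  mets <- unique(table$metabolite)
  for (met in mets) {
    rows <- which(table$metabolite == met)
    idx <- sort(table$iso_index[rows])
    n <- table$carbon_count[[met]]
    expected <- 0:n
    if (!identical(idx, expected)) {
      missing_idx <- setdiff(expected, idx)
      add(met, NA_character_, "gap_in_isotopologue_indices",
          paste("missing m+", paste(missing_idx, collapse = ",m+"), sep = ""))
    }
  }
  vals <- table$values
  if (table$mode == "absolute") {
    neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      for (k in seq_len(nrow(neg))) {
        add(table$metabolite[neg[k, 1]], colnames(vals)[neg[k, 2]],
            "negative_value",
            sprintf("%s = %g", rownames(vals)[neg[k, 1]],
                    vals[neg[k, 1], neg[k, 2]]))
      }
    }
  } else {
    out <- which(!is.na(vals) & (vals < -tolerance | vals > 1 + tolerance),
                 arr.ind = TRUE)
    if (nrow(out)) {
      for (k in seq_len(nrow(out))) {
        add(table$metabolite[out[k, 1]], colnames(vals)[out[k, 2]],
            "proportion_out_of_range",
            sprintf("%s = %g", rownames(vals)[out[k, 1]],
                    vals[out[k, 1], out[k, 2]]))
      }
    }
    sums <- rowsum(vals, table$metabolite, na.rm = FALSE)
    bad <- which(!is.na(sums) & abs(sums - 1) > tolerance, arr.ind = TRUE)
    if (nrow(bad)) {
      for (k in seq_len(nrow(bad))) {
        add(rownames(sums)[bad[k, 1]], colnames(sums)[bad[k, 2]],
            "normalization",
            sprintf("sum of proportions = %.6g", sums[bad[k, 1], bad[k, 2]]))
      }
    }
  }
  if (length(v)) dplyr::bind_rows(v) else {
    tibble::tibble(metabolite = character(), sample = character(),
                   rule = character(), detail = character())
  }
}

# ---- tab-delimited IO -------------------------------------------------------

read_measurement_frame <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read an isotopologue table from a tab-delimited file
#'
#' Two dialects are accepted: (1) first column = feature id following the
#' `"metabolite_m+i"` convention; (2) two leading columns `metabolite` and
#' `isotopologue_index`. Remaining columns are samples.
#'
#' @param path file path.
#' @param mode `"absolute"` or `"proportion"`.
#' @return an [isotopologue_table()].
#' @export
read_isotopologue_table <- function(path, mode = c("absolute", "proportion")) {
  mode <- match.arg(mode)
  df <- read_measurement_frame(path)
  if (all(c("metabolite", "isotopologue_index") %in% names(df)[1:2])) {
    ids <- paste0(df$metabolite, "_m+", as.integer(df$isotopologue_index))
    m <- as.matrix(df[, -(1:2), drop = FALSE])
  } else {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  isotopologue_table(m, mode = mode)
}

#' Read a per-metabolite table (abundance or fractional contribution)
#'
#' @param path file path; first column = metabolite id, rest = samples.
#' @param quantity `"total_abundance"` or `"fractional_contribution"`.
#' @return a [metabolite_table()].
#' @export
read_metabolite_table <- function(path,
                                  quantity = c("total_abundance",
                                               "fractional_contribution")) {
  quantity <- match.arg(quantity)
  df <- read_measurement_frame(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  metabolite_table(m, quantity = quantity)
}

#' Read a sample sheet from a tab-delimited file
#' @param path file path with columns `sample_id`, `condition`,
#'   `timepoint_name`, `timepoint_hours`, `replicate`.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  sample_sheet(read_measurement_frame(path))
}

write_matrix_tsv <- function(values, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(values), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- id_col
  for (s in colnames(values)) df[[s]] <- fmt_full(values[, s])
  con <- file(path, open = "wb") # wb: unix newlines on every platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a measurement table to a tab-delimited file
#'
#' Numeric values are written at full double precision (`%.17g`), so a
#' write/read round trip reproduces them exactly; period decimal separator,
#' UTF-8, Unix newlines.
#'
#' @param table an [isotopologue_table()] or [metabolite_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(table, path) {
  if (inherits(table, "IsotopologueTable")) {
    write_matrix_tsv(table$values, path, id_col = "feature_id")
  } else if (inherits(table, "MetaboliteTable")) {
    write_matrix_tsv(table$values, path, id_col = "metabolite")
  } else {
    stop("not a measurement table", call. = FALSE)
  }
}

#' Write a sample sheet to a tab-delimited file
#' @param sheet a [sample_sheet()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(as.data.frame(sheet), con, sep = "\t", quote = FALSE,
              row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
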