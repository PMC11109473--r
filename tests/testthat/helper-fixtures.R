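# small in-code fixtures shared across test files

# isotopologue matrix from a list of per-metabolite MDV-by-sample matrices:
# iso_mat(pyr = rbind(c(10, 0), c(30, 0), c(60, 0)), samples = c("s1","s2"))
iso_mat <- function(..., samples) {
  blocks <- list(...)
  rows <- do.call(rbind, unname(blocks))
  ids <- unlist(lapply(names(blocks), function(met)
    paste0(met, "_m+", seq_len(nrow(blocks[[met]])) - 1)))
  dimnames(rows) <- list(ids, samples)
  rows
}

two_condition_sheet <- function(reps = 3,
                                conditions = c("Control", "KO"),
                                hours = 48) {
  grid <- expand.grid(replicate = seq_len(reps), condition = conditions,
                      stringsAsFactors = FALSE)
  sample_sheet(data.frame(
    sample_id = sprintf("%s_%d", grid$condition, grid$replicate),
    condition = grid$condition,
    timepoint_name = paste0("T", hours),
    timepoint_hours = hours,
    replicate = grid$replicate))
}

# deterministic small absolute-mode dataset: 3 metabolites, 2 conditions x 3
small_dataset <- function(seed = 11) {
  sheet <- two_condition_sheet()
  met_n <- c(ala = 3, asp = 4, glu = 5)
  set.seed(seed)
  vals <- do.call(rbind, lapply(names(met_n), function(met) {
    n <- met_n[[met]]
    m <- matrix(rlnorm((n + 1) * nrow(sheet), meanlog = 8, sdlog = 0.3),
                nrow = n + 1)
    rownames(m) <- paste0(met, "_m+", 0:n)
    m
  }))
  colnames(vals) <- sheet$sample_id
  harmonize_inputs(isotopologue_table(vals, "absolute"), sheet = sheet)
}

expect_no_violation <- function(table, tolerance = 0.02) {
  v <- validate_isotopologue_table(table, tolerance)
  expect_identical(nrow(v), 0L)
}
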