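test_that("total abundance is the per-sample sum of isotopologues", {
  m <- iso_mat(pyr = rbind(c(10, 0, 1), c(30, 0, NA), c(60, 0, 2)),
               samples = c("s1", "s2", "s3"))
  ab <- total_abundance(isotopologue_table(m, "absolute"))
  expect_identical(ab$quantity, "total_abundance")
  expect_equal(ab$values["pyr", "s1"], 100)
  expect_equal(ab$values["pyr", "s2"], 0)       # all-zero vector sums to 0
  expect_true(is.na(ab$values["pyr", "s3"]))    # missing Mi propagates

  # brute-force re-summation oracle on a random 50-metabolite table
  set.seed(21)
  mets <- paste0("met", 1:50)
  blocks <- lapply(mets, function(x) matrix(runif(4 * 6), 4))
  names(blocks) <- mets
  big <- do.call(iso_mat, c(blocks, list(samples = paste0("s", 1:6))))
  got <- total_abundance(isotopologue_table(big, "absolute"))$values
  for (met in mets) {
    rows <- paste0(met, "_m+", 0:3)
    for (s in paste0("s", 1:6)) {
      expect_equal(got[met, s], sum(big[rows, s]))
    }
  }
})

test_that("proportions normalize each MDV and map zero totals to missing", {
  m <- iso_mat(pyr = rbind(c(10, 0), c(30, 0), c(60, 0)),
               samples = c("s1", "s2"))
  pr <- isotopologue_proportions(isotopologue_table(m, "absolute"))
  expect_identical(pr$mode, "proportion")
  expect_equal(unname(pr$values[, "s1"]), c(0.10, 0.30, 0.60))
  expect_true(all(is.na(pr$values[, "s2"])))    # 0/0 recorded as missing

  expect_error(isotopologue_proportions(pr), "proportion mode")
  expect_error(total_abundance(pr), "absolute")
})

test_that("derived proportions sum to one wherever defined", {
  set.seed(31)
  blocks <- lapply(1:20, function(i) matrix(rlnorm(5 * 4), 5))
  names(blocks) <- paste0("m", 1:20)
  tbl <- isotopologue_table(
    do.call(iso_mat, c(blocks, list(samples = paste0("s", 1:4)))),
    "absolute")
  pr <- isotopologue_proportions(tbl)
  sums <- rowsum(pr$values, pr$metabolite)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_no_violation(pr, tolerance = 1e-9)
})

test_that("fractional contribution matches the carbon-weighted mean formula", {
  # n = 2, c = (0.25, 0.50, 0.25) -> (0.50*1 + 0.25*2)/2 = 0.5
  m <- iso_mat(gly = rbind(c(0.25), c(0.50), c(0.25)), samples = "s1")
  phi <- fractional_contribution(isotopologue_table(m, "proportion"))
  expect_equal(phi$values["gly", "s1"], 0.5, tolerance = 1e-12)
  expect_identical(phi$quantity, "fractional_contribution")

  # boundary cases: unlabeled and fully labeled
  ends <- iso_mat(a = rbind(c(1), c(0), c(0), c(0)),
                  b = rbind(c(0), c(0), c(0), c(1)), samples = "s1")
  phi2 <- fractional_contribution(isotopologue_table(ends, "proportion"))
  expect_identical(phi2$values["a", "s1"], 0)
  expect_identical(phi2$values["b", "s1"], 1)
})

test_that("composition identity and scale invariance hold", {
  set.seed(41)
  blocks <- lapply(1:10, function(i) matrix(rlnorm(6 * 3), 6))
  names(blocks) <- paste0("m", 1:10)
  raw <- do.call(iso_mat, c(blocks, list(samples = c("s1", "s2", "s3"))))
  tbl <- isotopologue_table(raw, "absolute")
  phi <- fractional_contribution(isotopologue_proportions(tbl))$values
  # direct evaluation from absolutes: sum_j(Mj*j) / (n * sum_j Mj)
  for (met in paste0("m", 1:10)) {
    rows <- paste0(met, "_m+", 0:5)
    direct <- colSums(raw[rows, ] * (0:5)) / (5 * colSums(raw[rows, ]))
    expect_equal(unname(phi[met, ]), unname(direct), tolerance = 1e-12)
  }
  # multiplying one (metabolite, sample) cell by k > 0 changes nothing
  scaled <- raw
  scaled[paste0("m3_m+", 0:5), "s2"] <- scaled[paste0("m3_m+", 0:5), "s2"] * 137
  tbl2 <- isotopologue_table(scaled, "absolute")
  expect_equal(isotopologue_proportions(tbl2)$values,
               isotopologue_proportions(tbl)$values, tolerance = 1e-12)
  expect_equal(fractional_contribution(isotopologue_proportions(tbl2))$values,
               phi, tolerance = 1e-12)
})

test_that("harmonize derives every quantity from absolute isotopologues", {
  ds <- small_dataset()
  expect_s3_class(ds$isotopologue_prop, "IsotopologueTable")
  expect_s3_class(ds$abundance, "MetaboliteTable")
  expect_s3_class(ds$fractional, "MetaboliteTable")
  expect_identical(colnames(ds$abundance$values), ds$sample_sheet$sample_id)
})

test_that("proportion-only input leaves abundances unavailable", {
  sheet <- two_condition_sheet(reps = 1)
  p <- iso_mat(ala = rbind(c(0.2, 0.1), c(0.3, 0.4), c(0.5, 0.5)),
               samples = sheet$sample_id)
  ds <- harmonize_inputs(isotopologue_table(p, "proportion"), sheet = sheet)
  expect_null(ds$abundance)
  expect_s3_class(ds$fractional, "MetaboliteTable")
  expect_true(any(grepl("unavailable", ds$log)))
})

test_that("supplied tables win over derived ones and discrepancies are logged", {
  sheet <- two_condition_sheet(reps = 1)
  m <- iso_mat(ala = rbind(c(10, 20), c(30, 30), c(60, 50)),
               samples = sheet$sample_id)
  supplied <- metabolite_table(
    matrix(c(999, 100), nrow = 1, dimnames = list("ala", sheet$sample_id)),
    "total_abundance")
  ds <- harmonize_inputs(isotopologue_table(m, "absolute"),
                         abundances = supplied, sheet = sheet)
  expect_identical(ds$abundance$values["ala", ], supplied$values["ala", ])
  expect_true(any(grepl("disagrees", ds$log)))
})

test_that("percentage-scale proportions are auto-detected and rescaled", {
  sheet <- two_condition_sheet(reps = 1)
  p <- iso_mat(ala = rbind(c(20, 10), c(30, 40), c(50, 50)),
               samples = sheet$sample_id)
  ds <- harmonize_inputs(isotopologue_table(p, "proportion"), sheet = sheet)
  expect_equal(sum(ds$isotopologue_prop$values[, 1]), 1)
  expect_true(any(grepl("percentages", ds$log)))
})

test_that("samples missing from the sheet raise an alignment error", {
  sheet <- two_condition_sheet(reps = 1)
  m <- iso_mat(ala = rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)),
               samples = c(sheet$sample_id, "orphan"))
  expect_error(harmonize_inputs(isotopologue_table(m, "absolute"),
                                sheet = sheet),
               "orphan")
})
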