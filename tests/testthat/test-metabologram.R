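toy_results <- function() {
  tibble::tibble(feature_id = c("AKG", "Glutamate", "Malate"),
                 effect = c(1, -1, 0.4),
                 p_adj = c(0.01, 0.02, 0.5))
}

toy_deg <- function() {
  deg_table(tibble::tibble(gene = c("OGDHL", "GLUL", "IDH1"),
                           effect = c(2, -2, 0.1),
                           p_adj = c(0.001, 0.04, 0.9)))
}

test_that("metabologram assembles rings, domain and neutral fills", {
  pw <- pathway_definition("TCA", metabolites = c("AKG", "Glutamate"),
                           genes = c("OGDHL", "GLUL"))
  mg <- build_metabologram(pw, toy_results(), toy_deg(), alpha = 0.05)
  expect_identical(mg$value_domain, c(-2, 2)) # symmetric max over both omics
  expect_identical(nrow(mg$segments), 4L)
  expect_identical(mg$segments$ring, rep(c("metabolite", "gene"), each = 2))
  # alphabetical within ring
  expect_identical(mg$segments$id, c("AKG", "Glutamate", "GLUL", "OGDHL"))

  # unmeasured member: neutral value, flagged not measured
  pw2 <- pathway_definition("TCA", metabolites = c("AKG", "Unseen"),
                            genes = "OGDHL")
  mg2 <- build_metabologram(pw2, toy_results(), toy_deg())
  seg <- mg2$segments[mg2$segments$id == "Unseen", ]
  expect_identical(seg$value, 0)
  expect_false(seg$measured)
  expect_false(seg$significant)

  # non-significant members carry FALSE flags
  ns <- toy_results(); ns$p_adj <- rep(0.9, 3)
  deg_ns <- toy_deg(); deg_ns$p_adj <- rep(0.9, 3)
  mg3 <- build_metabologram(pw, ns, deg_ns)
  expect_false(any(mg3$segments$significant))
})

test_that("per-omics scaling is odd-symmetric under global negation", {
  pw <- pathway_definition("TCA", metabolites = c("AKG", "Glutamate",
                                                  "Malate"),
                           genes = c("OGDHL", "GLUL", "IDH1"))
  res <- toy_results(); deg <- toy_deg()
  mg_pos <- build_metabologram(pw, res, deg)
  res_neg <- res; res_neg$effect <- -res_neg$effect
  deg_neg <- deg; deg_neg$effect <- -deg_neg$effect
  mg_neg <- build_metabologram(pw, res_neg, deg_neg)
  expect_equal(mg_neg$segments$value_scaled, -mg_pos$segments$value_scaled)
  expect_identical(mg_neg$value_domain, mg_pos$value_domain)
  # palette indices mirror exactly about the midpoint
  col_pos <- metabologram_colors(mg_pos)
  col_neg <- metabologram_colors(mg_neg)
  expect_identical(col_neg$palette_index, -col_pos$palette_index)
})

test_that("metabologram is invariant to member order and foreign genes", {
  res <- toy_results(); deg <- toy_deg()
  a <- build_metabologram(
    pathway_definition("P", c("AKG", "Glutamate"), c("OGDHL", "GLUL")),
    res, deg)
  b <- build_metabologram(
    pathway_definition("P", c("Glutamate", "AKG"), c("GLUL", "OGDHL")),
    res, deg)
  expect_identical(a$segments, b$segments)
  # removing a gene that is not a pathway member changes nothing
  deg2 <- deg[deg$gene != "IDH1", ]
  c2 <- build_metabologram(
    pathway_definition("P", c("AKG", "Glutamate"), c("OGDHL", "GLUL")),
    res, deg2)
  expect_identical(a$segments, c2$segments)
})

test_that("one-sided pathways warn but still emit the present ring", {
  pw <- pathway_definition("AA", metabolites = "AKG")
  expect_warning(mg <- build_metabologram(pw, toy_results(), toy_deg()),
                 "one omics")
  expect_identical(mg$segments$ring, "metabolite")
})

test_that("pathway files round-trip through the tab-delimited dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tmember_type\tmember_id",
               "TCA\tmetabolite\tAKG", "TCA\tgene\tOGDHL",
               "AA\tmetabolite\tGlutamate"), f)
  pws <- read_pathways(f)
  expect_setequal(names(pws), c("TCA", "AA"))
  expect_identical(pws$TCA$metabolites, "AKG")
  expect_identical(pws$TCA$genes, "OGDHL")
})

test_that("hypothesized-slow edges fire exactly on the stated rule", {
  edges <- data.frame(source = c("OGDHL", "AKG"), target = c("AKG", "Glutamate"))
  nodes <- data.frame(node_id = c("OGDHL", "AKG", "Glutamate"),
                      node_type = c("gene", "metabolite", "metabolite"))
  abun <- tibble::tibble(feature_id = c("AKG", "Glutamate"),
                         effect = c(1.2, 0.3), p_adj = c(0.01, 0.6))
  frac <- tibble::tibble(feature_id = c("AKG", "Glutamate"),
                         effect = c(-0.2, -0.1), p_adj = c(0.01, 0.7))
  net <- project_subnetwork(edges, nodes, abun, frac, toy_deg(), alpha = 0.05)
  # AKG: enrichment significantly down, abundance up -> incoming edge slow
  expect_identical(net$edges$style[net$edges$target == "AKG"],
                   "hypothesized-slow")
  # Glutamate: enrichment decrease not significant -> solid
  expect_identical(net$edges$style[net$edges$target == "Glutamate"], "solid")
  expect_identical(net$nodes$shape,
                   c("rectangle", "oval", "oval"))
  expect_true(net$nodes$differential[net$nodes$node_id == "AKG"])

  # no significant features -> all edges solid
  frac_ns <- frac; frac_ns$p_adj <- c(0.9, 0.9)
  abun_ns <- abun; abun_ns$p_adj <- c(0.9, 0.9)
  net2 <- project_subnetwork(edges, nodes, abun_ns, frac_ns, toy_deg())
  expect_true(all(net2$edges$style == "solid"))

  # abundance-only significance never triggers the slow style
  frac3 <- frac; frac3$p_adj <- c(0.9, 0.9)
  net3 <- project_subnetwork(edges, nodes, abun, frac3, toy_deg())
  expect_true(all(net3$edges$style == "solid"))
  expect_true(net3$nodes$differential[net3$nodes$node_id == "AKG"])

  # significant enrichment decrease with decreased abundance: not slow
  abun4 <- abun; abun4$effect <- c(-1.2, 0.3)
  net4 <- project_subnetwork(edges, nodes, abun4, frac, toy_deg())
  expect_identical(net4$edges$style[net4$edges$target == "AKG"], "solid")

  expect_error(project_subnetwork(
    data.frame(source = "ghost", target = "AKG"), nodes, abun, frac,
    toy_deg()), "ghost")
})

test_that("synthetic DEG tables carry their configured truth", {
  genes <- c("OGDHL", "GLUL", paste0("null", 1:20))
  deg <- generate_deg_table(genes, effects = c(OGDHL = 2, GLUL = -1.5),
                            alpha = 0.05, seed = 8)
  expect_identical(deg, generate_deg_table(genes,
                                           effects = c(OGDHL = 2,
                                                       GLUL = -1.5),
                                           alpha = 0.05, seed = 8))
  expect_equal(deg$effect[deg$gene == "OGDHL"], 2, tolerance = 0.2)
  expect_true(all(deg$p_adj[deg$configured] <= 0.05))
  expect_true(all(deg$p_adj[!deg$configured] > 0.05))
  # all-null spec: nothing passes alpha
  null_deg <- generate_deg_table(genes, seed = 8)
  expect_identical(sum(null_deg$p_adj <= 0.05), 0L)
  # end-to-end: metabologram significant segments = configured members
  pw <- pathway_definition("TCA", metabolites = "AKG",
                           genes = c("OGDHL", "null1"))
  mg <- build_metabologram(pw, toy_results(), deg)
  gene_seg <- mg$segments[mg$segments$ring == "gene", ]
  expect_true(gene_seg$significant[gene_seg$id == "OGDHL"])
  expect_false(gene_seg$significant[gene_seg$id == "null1"])
})
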