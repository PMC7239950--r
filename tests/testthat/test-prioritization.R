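test_that("patient estimate multiplies incidence, heterozygosity, LOH, 0.5", {
  pi1 <- patients_per_year(1735350, heterozygosity(0.177), 0.09)
  expect_equal(pi1, round(1735350 * 2 * 0.177 * 0.823 * 0.09 * 0.5))
  expect_lt(abs(pi1 - 22470) / 22470, 0.02)   # printed inputs are rounded
  expect_equal(patients_per_year(1735350, 0.3, 0), 0)
  # linearity pre-rounding, monotone in each argument
  expect_equal(patients_per_year(1e6, 0.4, 0.4), 2 * patients_per_year(5e5, 0.4, 0.4))
  expect_lte(patients_per_year(1e6, 0.2, 0.1), patients_per_year(1e6, 0.2, 0.2))
  expect_error(patients_per_year(-1, 0.2, 0.1), "negative")
  expect_error(patients_per_year(1e6, 0.6, 0.1), "0.5")
})

test_that("DEMETER2 dependency classification uses an inclusive -0.5 cut", {
  expect_true(classify_dependency(rep(-0.52, 5))$strong)
  expect_false(classify_dependency(rep(-0.14, 5))$strong)
  expect_true(classify_dependency(rep(-0.5, 5))$strong)    # boundary
  expect_true(is.na(classify_dependency(c(NA, NA))$strong))
  expect_equal(classify_dependency(c(-1, 0, -0.6, NA))$median, -0.6)
})

test_that("enrichment test is an exact one-sided binomial against background", {
  expect_lt(enrichment_test(413, 1183, 623, 17212), 1e-4)
  expect_gt(enrichment_test(50, 1000, 500, 10000), 0.4)   # equal proportions
  expect_gt(enrichment_test(0, 100, 50, 100), 0.99)       # depletion
  expect_error(enrichment_test(10, 5, 1, 10), "exceed")
  # agrees with brute-force upper-tail summation for small n
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:50, 1); k <- sample(0:n, 1)
    p0 <- round(runif(1, 0.05, 0.95) * 1e6) / 1e6
    brute <- sum(dbinom(k:n, n, p0))
    expect_equal(enrichment_test(k, n, p0 * 1e6, 1e6), brute,
                 tolerance = 1e-9)
  }
})

test_that("charge changes follow physiological-pH classes", {
  expect_true(charge_change(classify_protein_change("D", "A", 1)))
  expect_true(charge_change(classify_protein_change("P", "H", 1)))  # H positive
  expect_false(charge_change(classify_protein_change("L", "V", 1)))
  expect_false(charge_change(classify_protein_change("D", "E", 1)))  # same class
  expect_true(charge_change(classify_protein_change("K", "E", 1)))
  expect_true(charge_change(classify_protein_change("A", "AK", 1)))  # charged ins
  expect_false(charge_change(classify_protein_change("A", "AG", 1)))
  expect_true(charge_change(classify_protein_change("AK", "A", 1)))  # charged del
})

test_that("cysteine introduction is one-allele-only", {
  expect_true(introduces_cysteine(classify_protein_change("R", "C", 1)))
  expect_true(introduces_cysteine(classify_protein_change("C", "R", 1)))
  expect_false(introduces_cysteine(classify_protein_change("R", "K", 1)))
  expect_true(introduces_cysteine(classify_protein_change("A", "AC", 1)))
  expect_false(introduces_cysteine(classify_protein_change("CA", "CG", 2)))
})

test_that("composite score recounts its seven criteria", {
  all_on <- druggability_annotation(TRUE, TRUE, 95, TRUE, 4L, TRUE, TRUE)
  expect_equal(composite_score(all_on), 7L)
  expect_equal(composite_score(druggability_annotation()), 0L)
  # brute-force recount over random annotations
  set.seed(17)
  for (i in 1:50) {
    a <- druggability_annotation(
      has_ligand_bound_structure = runif(1) < 0.5,
      structure_druggable_or_tractable = runif(1) < 0.5,
      ligand_druggability_percentile = runif(1, 0, 100),
      has_ec_number = runif(1) < 0.5,
      visual_pocket_score = sample(0:4, 1),
      charge_altering = runif(1) < 0.5,
      introduces_cysteine = runif(1) < 0.5)
    manual <- sum(c(a$has_ligand_bound_structure,
                    a$structure_druggable_or_tractable,
                    a$ligand_druggability_percentile >= 90,
                    a$has_ec_number, a$visual_pocket_score >= 3,
                    a$charge_altering, a$introduces_cysteine))
    expect_equal(composite_score(a), manual)
    expect_true(composite_score(a) %in% 0:7)
  }
  expect_error(druggability_annotation(visual_pocket_score = 5L), "0..4")
})

test_that("Yates chi-square matches hand computation and symmetry", {
  res <- yates_chi_square(matrix(c(40, 0, 60, 100), 2))
  expect_equal(res$statistic, 47.53125)
  expect_lt(res$p, 1e-10)
  # equal to its expecteds -> 0 after clamping
  flat <- matrix(c(20, 20, 80, 80), 2)
  expect_equal(yates_chi_square(flat)$statistic, 0)
  expect_equal(yates_chi_square(flat)$p, 1)
  # transposition invariance, and agreement with stats::chisq.test
  tb <- matrix(c(13, 7, 22, 41), 2)
  expect_equal(yates_chi_square(tb)$statistic, yates_chi_square(t(tb))$statistic)
  ref <- suppressWarnings(chisq.test(tb, correct = TRUE))
  expect_equal(yates_chi_square(tb)$statistic, unname(ref$statistic))
  expect_equal(yates_chi_square(tb)$p, ref$p.value)
  expect_error(yates_chi_square(matrix(c(0, 0, 5, 5), 2)), "marginal")
})

test_that("compendium assembly joins variants to essential genes only", {
  calls <- data.frame(gene_symbol = c("G1", "G2", "G3"),
                      final_essential = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  catalog <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    gene_symbol = c("G1", "G1", "G2", "G3"),
    chromosome = "1", position = c(10L, 20L, 30L, 40L),
    ref_allele = "A", alt_allele = "G",
    consequence_class = "missense_variant",
    maf = c(0.177, 0.05, 0.3, 0.4), filter_status = "PASS",
    stringsAsFactors = FALSE)
  loh <- data.frame(gene_symbol = c("G1", "G2"), stratum = "pan_cancer",
                    n_called = 100L, n_loh = c(9L, 0L),
                    n_copy_neutral = 0L, rate = c(0.09, 0),
                    copy_neutral_share = NA, stringsAsFactors = FALSE)
  comp <- assemble_compendium(calls, catalog, loh)
  expect_equal(nrow(comp), 3L)          # hand-counted join
  expect_equal(comp$variant_id, c("v1", "v2", "v3"))
  expect_equal(comp$loh_rate_pan, c(0.09, 0.09, 0))
  # LOH rate 0 annotates but does not drop the row
  expect_true("v3" %in% comp$variant_id)
  expect_equal(comp$patients_per_year[1],
               patients_per_year(chi = heterozygosity(0.177), lam = 0.09))
  # no essential genes -> empty
  none <- transform(calls, final_essential = FALSE)
  expect_equal(nrow(assemble_compendium(none, catalog, loh)), 0L)
  # gene without LOH rates -> row kept, LOH columns missing, warning raised
  calls2 <- data.frame(gene_symbol = "G9", final_essential = TRUE)
  cat2 <- transform(catalog[1, ], gene_symbol = "G9")
  expect_warning(c2 <- assemble_compendium(calls2, cat2, loh), "without LOH")
  expect_true(is.na(c2$loh_rate_pan))
})
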