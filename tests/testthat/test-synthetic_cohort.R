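test_that("config validation rejects inconsistent settings", {
  expect_error(simulation_config(maf_low = 0.3, maf_high = 0.2), "maf_low")
  expect_error(simulation_config(n_genes = 10, n_essential = 20),
               "n_essential")
  expect_error(simulation_config(pam_overlap_fraction = 1.5), "fractions")
  expect_error(simulation_config(
    n_samples_per_type = c(A = 5L),
    loh_rate_per_type = c(B = 0.1)), "same types")
})

test_that("all generators are deterministic under the seed", {
  cfg <- tiny_config(seed = 42)
  v1 <- simulate_variants(cfg); v2 <- simulate_variants(cfg)
  expect_identical(v1$variants, v2$variants)
  expect_identical(lapply(v1$contexts, `[[`, "window"),
                   lapply(v2$contexts, `[[`, "window"))
  expect_identical(simulate_allelic_segments(cfg),
                   simulate_allelic_segments(cfg))
  s1 <- simulate_screens(cfg); s2 <- simulate_screens(cfg)
  expect_identical(s1$ceres, s2$ceres)
  expect_identical(s1$gene_trap, s2$gene_trap)
  a1 <- simulate_annotations(cfg, v1$variants)
  a2 <- simulate_annotations(cfg, v2$variants)
  expect_identical(a1$annotations, a2$annotations)
  # a different seed gives different draws
  expect_false(identical(simulate_variants(tiny_config(seed = 43))$variants,
                         v1$variants))
})

test_that("variant decoys are controllable and absent when disabled", {
  cfg <- tiny_config(decoy_subthreshold_fraction = 0,
                     decoy_nonpass_fraction = 0)
  sim <- simulate_variants(cfg)
  expect_equal(nrow(filter_common_variants(sim$variants)),
               nrow(sim$variants))
  cfg2 <- tiny_config(decoy_subthreshold_fraction = 0.2,
                      decoy_nonpass_fraction = 0.2)
  sim2 <- simulate_variants(cfg2)
  expect_lt(nrow(filter_common_variants(sim2$variants)),
            nrow(sim2$variants))
  expect_true(any(sim2$variants$maf < 0.01))
  expect_true(any(sim2$variants$filter_status != "PASS"))
})

test_that("planted PAM-specific contexts verify against the oracle", {
  cfg <- tiny_config(seed = 3, pam_overlap_fraction = 1)
  sim <- simulate_variants(cfg)
  snv <- sim$variants$variant_id[nchar(sim$variants$ref_allele) == 1 &
                                   nchar(sim$variants$alt_allele) == 1]
  planted <- intersect(sim$planted_pam_specific, snv)
  expect_gt(length(planted), 10)
  for (id in planted) {
    ctx <- sim$contexts[[id]]
    want <- oracle_allele_specific(ctx$window, ctx$variant_offset,
                                   ctx$ref_allele, ctx$alt_allele)
    expect_true(want$is_specific, info = id)
  }
  # non-planted contexts are verified non-specific
  others <- setdiff(names(sim$contexts), sim$planted_pam_specific)
  for (id in others[seq_len(min(20, length(others)))]) {
    ctx <- sim$contexts[[id]]
    expect_false(allele_specific_pam(ctx)$is_specific, info = id)
  }
  # window carries the reference allele at the offset by construction
  for (ctx in sim$contexts[1:10])
    expect_equal(substr(ctx$window, ctx$variant_offset + 1,
                        ctx$variant_offset + nchar(ctx$ref_allele)),
                 ctx$ref_allele)
})

test_that("segment generator honours degenerate LOH settings", {
  none <- tiny_config(loh_rate_per_type = c(ACC = 0, LUAD = 0))
  seg <- simulate_allelic_segments(none)
  expect_true(all(seg$minor_cn >= 1))

  all_cn <- tiny_config(loh_rate_per_type = c(ACC = 1, LUAD = 1),
                        copy_neutral_fraction = 1)
  seg2 <- simulate_allelic_segments(all_cn)
  calls <- segments_to_gene_calls(seg2, make_gene_models(all_cn))
  expect_true(all(calls$loh_class == "copy_neutral"))
})

test_that("screen generator plants recoverable essential genes", {
  cfg <- tiny_config(seed = 8)
  scr <- simulate_screens(cfg)
  expect_equal(length(scr$planted_essential), cfg$n_essential)
  planted <- rownames(scr$ceres) %in% scr$planted_essential
  expect_lt(mean(scr$ceres[planted, ]), -0.8)
  expect_gt(mean(scr$ceres[!planted, ]), -0.2)
  # null case: no separation at zero effect
  null_cfg <- tiny_config(seed = 8, essential_effect = 0)
  null_scr <- simulate_screens(null_cfg)
  expect_lt(abs(mean(null_scr$ceres[planted, ]) -
                  mean(null_scr$ceres[!planted, ])), 0.2)
})

test_that("annotation generator is internally consistent", {
  cfg <- tiny_config(seed = 5)
  sim <- simulate_variants(cfg)
  ann <- simulate_annotations(cfg, sim$variants)
  expect_gt(length(ann$annotations), 0)
  for (id in names(ann$annotations)) {
    a <- ann$annotations[[id]]
    ch <- ann$changes[[id]]
    expect_equal(a$charge_altering, charge_change(ch))
    expect_equal(a$introduces_cysteine, introduces_cysteine(ch))
    expect_equal(composite_score(a),
                 sum(c(a$has_ligand_bound_structure,
                       a$structure_druggable_or_tractable,
                       a$ligand_druggability_percentile >= 90,
                       a$has_ec_number, a$visual_pocket_score >= 3,
                       a$charge_altering, a$introduces_cysteine)))
  }
})

test_that("fixture cohort round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_config(seed = 12)
  files <- write_fixture_cohort(cfg, dir)
  expect_true(all(file.exists(files)))
  v <- read_variants(files[["variants"]], dialect = "tsv")
  sim <- simulate_variants(cfg)
  expect_equal(v$maf, sim$variants$maf, tolerance = 1e-9)
  expect_equal(v$position, sim$variants$position)
  seg <- read_allelic_segments(files[["segments"]])
  expect_equal(seg$start, simulate_allelic_segments(cfg)$start)
  ctx <- read_fasta_contexts(files[["contexts"]])
  expect_equal(unname(ctx[sim$variants$variant_id[1]]),
               sim$contexts[[sim$variants$variant_id[1]]]$window)
  m <- read_matrix(files[["ceres"]])
  expect_equal(m, simulate_screens(cfg)$ceres, tolerance = 1e-9)
  ann <- read_druggability_annotations(files[["annotations"]])
  direct <- simulate_annotations(cfg, sim$variants)$annotations
  expect_equal(length(ann), length(direct))
  id <- names(direct)[1]
  expect_equal(composite_score(ann[[id]]), composite_score(direct[[id]]))
})
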