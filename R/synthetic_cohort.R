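# Synthetic-cohort generator. Emits inputs with the statistical structure
# the analysis assumes — a population variant catalog with controllable
# PAM-overlapping contexts, per-sample allelic segments with planted
# per-tumor-type LOH rates, and dependency-screen matrices with planted
# essential genes — so every downstream stage is testable without the
# population-scale source downloads it emulates.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: per-type
#' genome LOH rates spanning the observed range (45% down to ~0), a 28%
#' copy-neutral share among LOH events, common variants with MAF uniform on
#' \[0.01, 0.5\], roughly 3 variants per gene, and 23% of coding SNVs
#' placed so one allele completes a PAM.
#'
#' @param seed Integer seed; every generator is deterministic under it.
#' @param n_genes Number of genes.
#' @param n_essential Number of planted essential genes.
#' @param n_samples_per_type Named integer vector: samples per tumor type.
#' @param loh_rate_per_type Named fractions: planted per-gene LOH
#'   probability per tumor type.
#' @param copy_neutral_fraction Fraction of LOH events that are copy-neutral.
#' @param maf_low,maf_high Uniform MAF bounds for common variants.
#' @param mean_variants_per_gene Poisson mean variant count per gene.
#' @param pam_overlap_fraction Fraction of coding SNVs planted with an
#'   allele-specific PAM.
#' @param decoy_subthreshold_fraction,decoy_nonpass_fraction Fractions of
#'   additional decoy variants (rare, i.e. MAF < 0.01, and non-PASS).
#' @param n_cell_lines Cell lines per screen matrix.
#' @param essential_effect Dependency shift of planted essential genes: the
#'   planted CERES/DEMETER2 mean is `-2 * essential_effect`; 0 disables
#'   planting so essential and null genes are indistinguishable.
#' @param p_sense_essential Sense-insertion probability for essential genes
#'   in the gene-trap screen (null genes use 0.5).
#' @param mean_insertions Mean gene-trap insertion count per gene.
#' @param ccle_trigger_fraction Fraction of null genes given CCLE profiles
#'   that trigger each exclusion rule.
#' @param ccle_missing_fraction Fraction of essential genes with missing
#'   CCLE data (exercises the rescue rule).
#' @param annotation_prevalence Named numeric vector of prevalences for the
#'   independently drawn druggability criteria.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 1000L,
                              n_essential = 100L,
                              n_samples_per_type = c(ACC = 100L, LUAD = 100L,
                                                     PAAD = 100L, THCA = 100L),
                              loh_rate_per_type = c(ACC = 0.45, LUAD = 0.21,
                                                    PAAD = 0.09, THCA = 0.01),
                              copy_neutral_fraction = 0.28,
                              maf_low = 0.01, maf_high = 0.5,
                              mean_variants_per_gene = 3,
                              pam_overlap_fraction = 0.23,
                              decoy_subthreshold_fraction = 0.05,
                              decoy_nonpass_fraction = 0.05,
                              n_cell_lines = 25L,
                              essential_effect = 0.5,
                              p_sense_essential = 0.15,
                              mean_insertions = 50,
                              ccle_trigger_fraction = 0.01,
                              ccle_missing_fraction = 0.05,
                              annotation_prevalence = c(
                                has_ligand_bound_structure = 0.12,
                                structure_druggable_or_tractable = 0.39,
                                has_ec_number = 0.25)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_essential = as.integer(n_essential),
              n_samples_per_type = n_samples_per_type,
              loh_rate_per_type = loh_rate_per_type,
              copy_neutral_fraction = copy_neutral_fraction,
              maf_low = maf_low, maf_high = maf_high,
              mean_variants_per_gene = mean_variants_per_gene,
              pam_overlap_fraction = pam_overlap_fraction,
              decoy_subthreshold_fraction = decoy_subthreshold_fraction,
              decoy_nonpass_fraction = decoy_nonpass_fraction,
              n_cell_lines = as.integer(n_cell_lines),
              essential_effect = essential_effect,
              p_sense_essential = p_sense_essential,
              mean_insertions = mean_insertions,
              ccle_trigger_fraction = ccle_trigger_fraction,
              ccle_missing_fraction = ccle_missing_fraction,
              annotation_prevalence = annotation_prevalence)
  fracs <- c(cfg$loh_rate_per_type, cfg$copy_neutral_fraction, cfg$maf_low,
             cfg$maf_high, cfg$pam_overlap_fraction,
             cfg$decoy_subthreshold_fraction, cfg$decoy_nonpass_fraction,
             cfg$p_sense_essential, cfg$ccle_missing_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("config error: fractions must lie in [0,1]")
  if (cfg$maf_low >= cfg$maf_high)
    stop("config error: maf_low must be below maf_high")
  if (cfg$n_essential > cfg$n_genes)
    stop("config error: n_essential exceeds n_genes")
  if (cfg$n_genes < 1L || cfg$n_cell_lines < 1L ||
      any(cfg$n_samples_per_type < 1L))
    stop("config error: counts must be positive")
  if (!setequal(names(cfg$n_samples_per_type), names(cfg$loh_rate_per_type)))
    stop("config error: sample counts and LOH rates must name the same types")
  structure(cfg, class = "simulation_config")
}

gene_names <- function(config) sprintf("GENE%04d", seq_len(config$n_genes))

#' Deterministic synthetic gene layout
#'
#' Genes are placed round-robin on autosomes 1-22 as non-overlapping
#' 10-kb intervals separated by 90-kb gaps; the layout is a pure function
#' of `n_genes` (no randomness).
#'
#' @param config A [simulation_config()].
#' @return Gene-model data.frame as from [read_gene_bed()].
#' @export
make_gene_models <- function(config) {
  n <- config$n_genes
  idx <- seq_len(n) - 1L
  chrom <- as.character(idx %% 22L + 1L)
  slot <- idx %/% 22L
  start <- slot * 100000L + 50000L
  data.frame(gene_symbol = gene_names(config), chromosome = chrom,
             start = start, end = start + 10000L,
             is_autosome = TRUE, stringsAsFactors = FALSE)
}

#' Which planted genes are essential
#'
#' The planted essential set is a seed-deterministic sample of
#' `n_essential` gene symbols.
#'
#' @param config A [simulation_config()].
#' @return Character vector of gene symbols.
#' @export
planted_essential_genes <- function(config) {
  seed_stream(config$seed, 101L)
  sort(sample(gene_names(config), config$n_essential))
}

# local seed scoping: each generator derives its own stream from the config
# seed plus a fixed offset, so generators are individually deterministic
# and order-independent
seed_stream <- function(seed, offset) {
  set.seed((as.integer(seed) * 97L + offset) %% .Machine$integer.max)
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# draw a 61-nt window around a ref allele; when specific = TRUE the window
# and alt are constructed (then verified) so that exactly one allele
# carries a PAM overlapping the variant; when FALSE, resampled until no
# allele-specific PAM exists
draw_context <- function(variant_id, ref, alt, specific,
                         motifs = c("NGG", "NAG"), flank = 30L) {
  for (attempt in 1:200) {
    if (specific) {
      # plant the variant as the first G of an NGG: ref in {C,T} keeps both
      # motifs absent, alt = G completes NGG on the plus strand
      ref <- sample(c("C", "T"), 1L)
      alt <- "G"
      left <- random_dna(flank)
      right <- paste0("G", random_dna(flank - 1L))
      window <- paste0(left, ref, right)
    } else {
      window <- paste0(random_dna(flank), ref,
                       random_dna(flank + nchar(ref) - 1L))
      window <- substr(window, 1L, 2L * flank + nchar(ref))
    }
    ctx <- allele_context(variant_id, window, flank, ref, alt)
    asp <- allele_specific_pam(ctx, motifs)
    ok <- if (specific) asp$is_specific else !asp$is_specific
    if (ok) return(list(context = ctx, ref = ref, alt = alt))
  }
  stop("context sampling failed to satisfy the PAM constraint")
}

#' Simulate a population variant catalog with sequence contexts
#'
#' Each gene receives a Poisson number of variants with MAF uniform on
#' `[maf_low, maf_high]`; a fraction `pam_overlap_fraction` of coding
#' (non-UTR) SNVs is placed so that exactly one allele completes a PAM in
#' its 61-nt context, and every other variant's context is verified free of
#' allele-specific PAMs. Decoy variants (MAF below 0.01, and non-PASS
#' rows) are appended at the configured fractions so filter logic is
#' exercised.
#'
#' @param config A [simulation_config()].
#' @param genes Optional gene models (default [make_gene_models()]).
#' @return A list: `variants` (data.frame as from [read_variants()]),
#'   `contexts` (named list of [allele_context()]), and
#'   `planted_pam_specific` (character vector of variant ids).
#' @export
simulate_variants <- function(config, genes = make_gene_models(config)) {
  seed_stream(config$seed, 202L)
  classes <- consequence_classes()
  # coding-heavy class mix; indel classes kept rare
  weights <- stats::setNames(rep(0.02, length(classes)), classes)
  weights["missense_variant"] <- 0.40
  weights["synonymous_variant"] <- 0.20
  weights["3_prime_UTR_variant"] <- 0.10
  weights["5_prime_UTR_variant"] <- 0.06
  indel_classes <- c("inframe_insertion", "inframe_deletion",
                     "frameshift_variant")

  n_per_gene <- stats::rpois(nrow(genes), config$mean_variants_per_gene)
  gene_idx <- rep(seq_len(nrow(genes)), n_per_gene)
  n <- length(gene_idx)
  if (n == 0L) stop("no variants drawn; increase mean_variants_per_gene")
  cls <- sample(classes, n, replace = TRUE, prob = weights)
  pos <- genes$start[gene_idx] +
    floor(stats::runif(n) * (genes$end[gene_idx] - genes$start[gene_idx]))
  maf <- stats::runif(n, config$maf_low, config$maf_high)

  # decoys: sub-threshold MAF and non-PASS rows
  n_rare <- round(config$decoy_subthreshold_fraction * n)
  n_fail <- round(config$decoy_nonpass_fraction * n)
  decoy_kind <- c(rep("none", n), rep("rare", n_rare), rep("fail", n_fail))
  if (n_rare + n_fail > 0L) {
    extra_gene <- sample(seq_len(nrow(genes)), n_rare + n_fail, replace = TRUE)
    gene_idx <- c(gene_idx, extra_gene)
    cls <- c(cls, sample(classes, n_rare + n_fail, replace = TRUE,
                         prob = weights))
    pos <- c(pos, genes$start[extra_gene] + floor(stats::runif(n_rare + n_fail) *
               (genes$end[extra_gene] - genes$start[extra_gene])))
    maf <- c(maf, stats::runif(n_rare, 0.0005, 0.0095),
             stats::runif(n_fail, config$maf_low, config$maf_high))
  }
  total <- length(gene_idx)
  id <- sprintf("rs%06d", seq_len(total))
  is_indel <- cls %in% indel_classes
  ref <- character(total); alt <- character(total)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(total)) {
    if (is_indel[i]) {
      anchor <- sample(bases, 1L)
      ins <- paste(sample(bases, sample(1:3, 1L), replace = TRUE),
                   collapse = "")
      if (cls[i] == "inframe_deletion") {
        ref[i] <- paste0(anchor, ins); alt[i] <- anchor
      } else {
        ref[i] <- anchor; alt[i] <- paste0(anchor, ins)
      }
    } else {
      ref[i] <- sample(bases, 1L)
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    }
  }
  # choose which coding SNVs carry a planted allele-specific PAM
  orf_snv <- which(!is_indel & cls %in% orf_consequence_classes() &
                     decoy_kind == "none")
  n_pam <- round(config$pam_overlap_fraction * length(orf_snv))
  pam_idx <- if (n_pam > 0L) sample(orf_snv, n_pam) else integer()

  contexts <- vector("list", total)
  for (i in seq_len(total)) {
    drawn <- draw_context(id[i], ref[i], alt[i], specific = i %in% pam_idx)
    ref[i] <- drawn$ref; alt[i] <- drawn$alt
    contexts[[i]] <- drawn$context
  }
  names(contexts) <- id

  variants <- data.frame(
    variant_id = id,
    gene_symbol = genes$gene_symbol[gene_idx],
    chromosome = genes$chromosome[gene_idx],
    position = as.integer(pos),
    ref_allele = ref, alt_allele = alt,
    consequence_class = cls,
    maf = maf,
    filter_status = ifelse(decoy_kind == "fail", "other", "PASS"),
    stringsAsFactors = FALSE)
  list(variants = variants, contexts = contexts,
       planted_pam_specific = id[pam_idx])
}

#' Simulate per-sample allelic copy-number segments
#'
#' Per sample, each gene's covering segment loses its minor allele with the
#' tumor type's planted LOH probability; among LOH events a fraction
#' `copy_neutral_fraction` keeps total copy number (major 2, log2 relative
#' above -0.1) and the rest lose it (major 1, log2 at or below -0.1).
#' Non-LOH genes stay heterozygous (minor >= 1). Each gene segment is
#' flanked by neutral segments so overlap assignment is exercised.
#'
#' @param config A [simulation_config()].
#' @param genes Gene models (default [make_gene_models()]).
#' @return Segment data.frame as from [read_allelic_segments()].
#' @export
simulate_allelic_segments <- function(config,
                                      genes = make_gene_models(config)) {
  seed_stream(config$seed, 303L)
  types <- names(config$n_samples_per_type)
  pieces <- vector("list", length(types))
  for (t in seq_along(types)) {
    ty <- types[t]
    n_s <- config$n_samples_per_type[[ty]]
    rate <- config$loh_rate_per_type[[ty]]
    sample_ids <- sprintf("%s_S%04d", ty, seq_len(n_s))
    n_g <- nrow(genes)
    n <- n_s * n_g
    samp <- rep(sample_ids, each = n_g)
    gidx <- rep(seq_len(n_g), times = n_s)
    loh <- stats::runif(n) < rate
    neutral_loh <- loh & (stats::runif(n) < config$copy_neutral_fraction)
    minor <- ifelse(loh, 0L, 1L)
    major <- ifelse(neutral_loh, 2L, 1L)
    log2rel <- numeric(n)
    log2rel[!loh] <- stats::runif(sum(!loh), -0.08, 0.08)
    log2rel[loh & !neutral_loh] <- stats::runif(sum(loh & !neutral_loh),
                                                -1.0, -0.11)
    log2rel[neutral_loh] <- stats::runif(sum(neutral_loh), -0.05, 0.08)
    gene_seg <- data.frame(
      sample = samp, tumor_type = ty,
      chromosome = genes$chromosome[gidx],
      start = genes$start[gidx] - 2000L,
      end = genes$end[gidx] + 2000L,
      major_cn = major, minor_cn = minor,
      log2_relative = round(log2rel, 4),
      stringsAsFactors = FALSE)
    flank_left <- data.frame(
      sample = samp, tumor_type = ty,
      chromosome = genes$chromosome[gidx],
      start = genes$start[gidx] - 30000L,
      end = genes$start[gidx] - 2000L,
      major_cn = 1L, minor_cn = 1L, log2_relative = 0,
      stringsAsFactors = FALSE)
    pieces[[t]] <- rbind(gene_seg, flank_left)
  }
  d <- do.call(rbind, pieces)
  out <- data.frame(sample_id = d$sample, tumor_type = d$tumor_type,
                    chromosome = d$chromosome, start = d$start, end = d$end,
                    major_cn = d$major_cn, minor_cn = d$minor_cn,
                    log2_relative = d$log2_relative, stringsAsFactors = FALSE)
  out <- out[order(out$sample_id, out$chromosome, out$start), ]
  rownames(out) <- NULL
  out
}

#' Simulate dependency-screen evidence with planted essential genes
#'
#' Planted essential genes receive low q-values in the two CRISPR screens,
#' gene-trap insertions skewed against the sense orientation, and
#' CERES/DEMETER2 scores centered at `-2 * essential_effect`; null genes
#' receive balanced gene-trap counts, uniform q-values, and scores near
#' zero. A small subset of null genes gets CCLE profiles triggering each
#' exclusion rule, and a subset of essential genes gets missing CCLE data
#' to exercise the rescue rule. With `essential_effect = 0` no planting
#' occurs at all.
#'
#' @param config A [simulation_config()].
#' @return A list of class `essentiality_evidence`: matrices `crispr_q`
#'   (genes x 2), `gene_trap` (genes x 2: sense, antisense),
#'   `ccle_log2_cn`, `ccle_rpkm`, `ceres`, `demeter2` (genes x cell
#'   lines), and `planted_essential` (character vector).
#' @export
simulate_screens <- function(config) {
  essential <- planted_essential_genes(config)
  seed_stream(config$seed, 404L)
  genes <- gene_names(config)
  n <- config$n_genes
  L <- config$n_cell_lines
  is_ess <- genes %in% essential & config$essential_effect > 0
  lines <- sprintf("CL%03d", seq_len(L))

  crispr_q <- matrix(stats::runif(2L * n), nrow = n,
                     dimnames = list(genes, c("screen_kbm7", "screen_psc")))
  crispr_q[is_ess, ] <- stats::runif(2L * sum(is_ess), 0, 0.05)

  n_ins <- stats::rpois(n, config$mean_insertions) + 1L
  p_sense <- ifelse(is_ess, config$p_sense_essential, 0.5)
  sense <- stats::rbinom(n, n_ins, p_sense)
  gene_trap <- cbind(sense = sense, antisense = n_ins - sense)
  rownames(gene_trap) <- genes

  shift <- -2 * config$essential_effect
  ceres <- matrix(stats::rnorm(n * L, 0, 0.15), nrow = n,
                  dimnames = list(genes, lines))
  ceres[is_ess, ] <- ceres[is_ess, ] + shift
  demeter2 <- matrix(stats::rnorm(n * L, 0, 0.15), nrow = n,
                     dimnames = list(genes, lines))
  demeter2[is_ess, ] <- demeter2[is_ess, ] + shift

  ccle_cn <- matrix(stats::rnorm(n * L, 0, 0.3), nrow = n,
                    dimnames = list(genes, lines))
  ccle_rpkm <- matrix(stats::runif(n * L, 5, 100), nrow = n,
                      dimnames = list(genes, lines))
  # plant CCLE-exclusion profiles on null genes, one third per rule
  null_idx <- which(!is_ess)
  n_trig <- min(length(null_idx),
                3L * ceiling(config$ccle_trigger_fraction * length(null_idx)))
  if (n_trig >= 3L) {
    trig <- sample(null_idx, n_trig)
    thirds <- split(trig, rep(1:3, length.out = n_trig))
    ccle_cn[thirds[[1L]], 1:3] <- -6          # homdel in >2 lines
    ccle_rpkm[thirds[[2L]], 1:6] <- 0.1       # <0.5 RPKM in >5 lines
    ccle_cn[thirds[[3L]], 1L] <- -6           # homdel + low expression,
    ccle_rpkm[thirds[[3L]], 1L] <- 0.8        # same line
  }
  # missing CCLE data on a subset of essential genes (rescue exerciser)
  ess_idx <- which(is_ess)
  n_miss <- round(config$ccle_missing_fraction * length(ess_idx))
  if (n_miss > 0L) {
    miss <- sample(ess_idx, n_miss)
    ccle_cn[miss, ] <- NA_real_
    ccle_rpkm[miss, ] <- NA_real_
  }
  structure(list(crispr_q = crispr_q, gene_trap = gene_trap,
                 ccle_log2_cn = ccle_cn, ccle_rpkm = ccle_rpkm,
                 ceres = ceres, demeter2 = demeter2,
                 planted_essential = essential),
            class = "essentiality_evidence")
}

#' Simulate druggability annotations for protein-altering variants
#'
#' Missense and in-frame indel variants receive an amino-acid change drawn
#' at random; the charge and cysteine criteria are then computed from that
#' change (so they are consistent with it by construction), while the
#' structural/enzyme criteria are independent draws at the configured
#' prevalences and the visual pocket score and ligand percentile are drawn
#' uniformly.
#'
#' @param config A [simulation_config()].
#' @param variants Variant data.frame.
#' @return A list: `annotations` (named list of
#'   [druggability_annotation()]), `changes` (named list of
#'   [classify_protein_change()] results), keyed by variant id.
#' @export
simulate_annotations <- function(config, variants) {
  seed_stream(config$seed, 505L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]]
  sel <- variants$consequence_class %in%
    c("missense_variant", "inframe_insertion", "inframe_deletion")
  ids <- variants$variant_id[sel]
  cls <- variants$consequence_class[sel]
  prev <- config$annotation_prevalence
  annotations <- list(); changes <- list()
  for (i in seq_along(ids)) {
    pos <- sample(1:400, 1L)
    if (cls[i] == "missense_variant") {
      r <- sample(aa, 1L); a <- sample(setdiff(aa, r), 1L)
    } else if (cls[i] == "inframe_insertion") {
      r <- sample(aa, 1L)
      a <- paste0(r, paste(sample(aa, sample(1:2, 1L), replace = TRUE),
                           collapse = ""))
    } else {
      a <- sample(aa, 1L)
      r <- paste0(a, paste(sample(aa, sample(1:2, 1L), replace = TRUE),
                           collapse = ""))
    }
    ch <- classify_protein_change(r, a, pos)
    annotations[[ids[i]]] <- druggability_annotation(
      has_ligand_bound_structure =
        stats::runif(1) < prev[["has_ligand_bound_structure"]],
      structure_druggable_or_tractable =
        stats::runif(1) < prev[["structure_druggable_or_tractable"]],
      ligand_druggability_percentile = stats::runif(1, 0, 100),
      has_ec_number = stats::runif(1) < prev[["has_ec_number"]],
      visual_pocket_score = sample(0:4, 1L),
      charge_altering = charge_change(ch),
      introduces_cysteine = introduces_cysteine(ch))
    changes[[ids[i]]] <- ch
  }
  list(annotations = annotations, changes = changes)
}

#' Write a complete miniature synthetic cohort to a directory
#'
#' Emits exactly the formats the readers consume: `variants.tsv`,
#' `contexts.fasta`, `genes.bed`, `segments.tsv`, `crispr_q.csv`,
#' `gene_trap.tsv`, `ccle_log2_cn.csv`, `ccle_rpkm.csv`, `ceres.csv`,
#' `demeter2.csv`, `annotations.tsv`, `tsg.tsv`.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @param n_tsg Number of planted tumor-suppressor symbols (drawn from the
#'   non-essential genes).
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_cohort <- function(config, dir, n_tsg = 2L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  genes <- make_gene_models(config)
  sim <- simulate_variants(config, genes)
  seg <- simulate_allelic_segments(config, genes)
  scr <- simulate_screens(config)
  ann <- simulate_annotations(config, sim$variants)

  v <- sim$variants
  out_v <- data.frame(variant_id = v$variant_id, gene_symbol = v$gene_symbol,
                      chromosome = v$chromosome, position = v$position + 1L,
                      ref_allele = v$ref_allele, alt_allele = v$alt_allele,
                      consequence_class = v$consequence_class,
                      global_af = v$maf, filter_status = v$filter_status,
                      stringsAsFactors = FALSE)
  data.table::fwrite(out_v, p("variants.tsv"), sep = "\t", quote = FALSE)

  ctx_seq <- vapply(sim$contexts, function(x) x$window, character(1))
  write_fasta_contexts(ctx_seq, p("contexts.fasta"))

  bed <- data.frame(chrom = genes$chromosome, start = genes$start,
                    end = genes$end, name = genes$gene_symbol)
  data.table::fwrite(bed, p("genes.bed"), sep = "\t", quote = FALSE,
                     col.names = FALSE)

  out_s <- data.frame(sample = seg$sample_id, tumor_type = seg$tumor_type,
                      chromosome = seg$chromosome, start = seg$start + 1L,
                      end = seg$end, major_cn = seg$major_cn,
                      minor_cn = seg$minor_cn,
                      log2_relative = seg$log2_relative,
                      stringsAsFactors = FALSE)
  data.table::fwrite(out_s, p("segments.tsv"), sep = "\t", quote = FALSE)

  write_matrix(scr$crispr_q, p("crispr_q.csv"))
  data.table::fwrite(data.frame(gene_symbol = rownames(scr$gene_trap),
                                scr$gene_trap), p("gene_trap.tsv"),
                     sep = "\t", quote = FALSE)
  write_matrix(scr$ccle_log2_cn, p("ccle_log2_cn.csv"))
  write_matrix(scr$ccle_rpkm, p("ccle_rpkm.csv"))
  write_matrix(scr$ceres, p("ceres.csv"))
  write_matrix(scr$demeter2, p("demeter2.csv"))

  write_druggability_annotations(ann$annotations, ann$changes,
                                 p("annotations.tsv"))

  seed_stream(config$seed, 606L)
  non_ess <- setdiff(gene_names(config), scr$planted_essential)
  tsg <- sort(sample(non_ess, min(n_tsg, length(non_ess))))
  writeLines(c("gene_symbol", tsg), p("tsg.tsv"))

  invisible(c(variants = p("variants.tsv"), contexts = p("contexts.fasta"),
              genes = p("genes.bed"), segments = p("segments.tsv"),
              crispr_q = p("crispr_q.csv"), gene_trap = p("gene_trap.tsv"),
              ccle_log2_cn = p("ccle_log2_cn.csv"),
              ccle_rpkm = p("ccle_rpkm.csv"), ceres = p("ceres.csv"),
              demeter2 = p("demeter2.csv"),
              annotations = p("annotations.tsv"), tsg = p("tsg.tsv")))
}

#' Write or read druggability annotations as TSV
#'
#' @param annotations Named list of [druggability_annotation()].
#' @param changes Named list of [classify_protein_change()] results (same
#'   keys); written as an HGVS-like short label column.
#' @param path TSV path.
#' @return `read_druggability_annotations` returns a named list of
#'   [druggability_annotation()] with the protein-change label attached as
#'   attribute `protein_change`.
#' @export
write_druggability_annotations <- function(annotations, changes, path) {
  ids <- names(annotations)
  d <- data.frame(
    variant_id = ids,
    protein_change = vapply(changes[ids], function(x) x$label, character(1)),
    has_ligand_bound_structure = vapply(annotations, `[[`, logical(1),
                                        "has_ligand_bound_structure"),
    structure_druggable_or_tractable = vapply(annotations, `[[`, logical(1),
                                              "structure_druggable_or_tractable"),
    ligand_druggability_percentile = vapply(annotations, `[[`, numeric(1),
                                            "ligand_druggability_percentile"),
    has_ec_number = vapply(annotations, `[[`, logical(1), "has_ec_number"),
    visual_pocket_score = vapply(annotations, `[[`, integer(1),
                                 "visual_pocket_score"),
    charge_altering = vapply(annotations, `[[`, logical(1), "charge_altering"),
    introduces_cysteine = vapply(annotations, `[[`, logical(1),
                                 "introduces_cysteine"),
    stringsAsFactors = FALSE)
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_druggability_annotations
#' @export
read_druggability_annotations <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  out <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    a <- druggability_annotation(
      has_ligand_bound_structure = d$has_ligand_bound_structure[i],
      structure_druggable_or_tractable = d$structure_druggable_or_tractable[i],
      ligand_druggability_percentile = d$ligand_druggability_percentile[i],
      has_ec_number = d$has_ec_number[i],
      visual_pocket_score = d$visual_pocket_score[i],
      charge_altering = d$charge_altering[i],
      introduces_cysteine = d$introduces_cysteine[i])
    attr(a, "protein_change") <- d$protein_change[i]
    out[[i]] <- a
  }
  stats::setNames(out, d$variant_id)
}
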