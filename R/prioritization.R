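# Target prioritization: patient-reach arithmetic, RNAi dependency class,
# druggability composite, supporting statistics, and compendium assembly.

#' Theoretical number of targetable new patients per year
#'
#' Multiplies the annual incidence `kappa` by the fraction of individuals
#' heterozygous at the locus (`chi`, Hardy-Weinberg 2pq), the pan-cancer LOH
#' rate of the gene (`lam`), and 0.5 — the fraction of LOH events expected
#' to remove the hypothetical targetable allele when the lost allele is
#' random. The product is rounded to the nearest whole patient.
#'
#' @param kappa New cancer cases per year; default 1,735,350 (US pan-cancer
#'   incidence).
#' @param chi Heterozygosity fraction in \[0, 0.5\].
#' @param lam Pan-cancer LOH rate in \[0, 1\].
#' @return Integer-valued estimate (vectorized).
#' @examples
#' patients_per_year(chi = heterozygosity(0.177), lam = 0.09)
#' @export
patients_per_year <- function(kappa = 1735350, chi, lam) {
  if (any(kappa < 0) || any(chi < 0) || any(lam < 0))
    stop("negative inputs")
  if (any(chi > 0.5)) stop("chi must not exceed 0.5 (Hardy-Weinberg 2pq)")
  if (any(lam > 1)) stop("lam must lie in [0, 1]")
  round(kappa * chi * lam * 0.5)
}

#' Classify RNAi dependency strength from DEMETER2 scores
#'
#' A gene is a moderately strong dependency when its median DEMETER2 score
#' across cell lines is at or below -0.5 (boundary inclusive).
#'
#' @param scores Per-cell-line DEMETER2 scores for one gene.
#' @param cut Threshold, default -0.5.
#' @return A list with `median` and `strong`; both `NA` without data.
#' @export
classify_dependency <- function(scores, cut = -0.5) {
  if (is.null(scores) || all(is.na(scores)))
    return(list(median = NA_real_, strong = NA))
  m <- stats::median(scores, na.rm = TRUE)
  list(median = m, strong = m <= cut)
}

#' One-sided binomial proportion enrichment test
#'
#' Exact binomial test of the subset proportion against the background
#' proportion, alternative "greater".
#'
#' @param k_subset,n_subset Successes and trials in the subset.
#' @param k_background,n_background Successes and trials in the background.
#' @return One-sided p-value.
#' @export
enrichment_test <- function(k_subset, n_subset, k_background, n_background) {
  if (k_subset > n_subset || k_background > n_background)
    stop("successes exceed trials")
  if (any(c(k_subset, n_subset, k_background, n_background) < 0))
    stop("negative counts")
  p0 <- k_background / n_background
  stats::binom.test(k_subset, n_subset, p = p0,
                    alternative = "greater")$p.value
}

# physiological-pH residue charge classes
residue_charge <- function(res) {
  ifelse(res %in% c("D", "E"), -1L,
         ifelse(res %in% c("K", "R", "H"), 1L, 0L))
}

check_residues <- function(x) {
  res <- strsplit(x, NULL)[[1]]
  bad <- setdiff(res, c(strsplit("ACDEFGHIKLMNPQRSTVWY", NULL)[[1]], "*"))
  if (length(bad) > 0L)
    stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
  res
}

#' Does a protein change alter residue charge?
#'
#' Charge classes at physiological pH: D and E negative; K, R and H
#' positive; all others (and stop) neutral. A missense change qualifies when
#' the two residues fall in different classes; an insertion or deletion
#' qualifies when any inserted or deleted residue is charged.
#'
#' @param change A [classify_protein_change()] result.
#' @return Logical.
#' @export
charge_change <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  ref <- check_residues(change$ref_residues)
  alt <- check_residues(change$alt_residues)
  if (change$kind == "missense")
    return(residue_charge(ref) != residue_charge(alt))
  # indel: charge is altered when the edited residues carry charge
  if (change$kind == "inframe_insertion") {
    inserted <- setdiff_multiset(alt, ref)
    return(any(residue_charge(inserted) != 0L))
  }
  if (change$kind == "inframe_deletion") {
    deleted <- setdiff_multiset(ref, alt)
    return(any(residue_charge(deleted) != 0L))
  }
  any(residue_charge(ref) != 0L) || any(residue_charge(alt) != 0L)
}

# multiset difference: elements of x minus (with multiplicity) elements of y
setdiff_multiset <- function(x, y) {
  for (e in y) {
    i <- match(e, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

#' Does a protein change introduce a cysteine in one allele?
#'
#' True when exactly one of the two residue strings contains a cysteine at
#' the affected position(s) — the allele pair can then be discriminated by
#' a covalent, cysteine-reactive approach.
#'
#' @param change A [classify_protein_change()] result.
#' @return Logical.
#' @export
introduces_cysteine <- function(change) {
  stopifnot(inherits(change, "protein_change"))
  ref_has <- "C" %in% check_residues(change$ref_residues)
  alt_has <- "C" %in% check_residues(change$alt_residues)
  xor(ref_has, alt_has)
}

#' Druggability annotation record
#'
#' @param has_ligand_bound_structure Protein has a small-molecule
#'   ligand-bound structure.
#' @param structure_druggable_or_tractable Structure predicted druggable or
#'   tractable.
#' @param ligand_druggability_percentile Ligand-based druggability
#'   percentile, 0-100.
#' @param has_ec_number Enzyme (EC number annotated).
#' @param visual_pocket_score Manual pocket score 0-4 (4 = variant near a
#'   pocket containing a small molecule).
#' @param charge_altering Variant alters residue charge.
#' @param introduces_cysteine Variant introduces a cysteine in one allele.
#' @return A list of class `druggability_annotation`.
#' @export
druggability_annotation <- function(has_ligand_bound_structure = FALSE,
                                    structure_druggable_or_tractable = FALSE,
                                    ligand_druggability_percentile = 0,
                                    has_ec_number = FALSE,
                                    visual_pocket_score = 0L,
                                    charge_altering = FALSE,
                                    introduces_cysteine = FALSE) {
  if (!visual_pocket_score %in% 0:4)
    stop("visual_pocket_score must be an integer in 0..4")
  if (ligand_druggability_percentile < 0 ||
      ligand_druggability_percentile > 100)
    stop("ligand_druggability_percentile must lie in [0, 100]")
  structure(list(
    has_ligand_bound_structure = isTRUE(has_ligand_bound_structure),
    structure_druggable_or_tractable = isTRUE(structure_druggable_or_tractable),
    ligand_druggability_percentile = as.numeric(ligand_druggability_percentile),
    has_ec_number = isTRUE(has_ec_number),
    visual_pocket_score = as.integer(visual_pocket_score),
    charge_altering = isTRUE(charge_altering),
    introduces_cysteine = isTRUE(introduces_cysteine)),
    class = "druggability_annotation")
}

#' Composite druggability score (0-7)
#'
#' Counts how many of seven prioritization analyses rank the variant among
#' the top candidates: ligand-bound structure; druggable-or-tractable
#' structure; ligand-based druggability in the top decile (percentile >=
#' 90); enzyme (EC number); visual pocket score >= 3 (variant in or near a
#' pocket); charge-altering; cysteine-introducing.
#'
#' @param annotation A [druggability_annotation()].
#' @return Integer 0-7.
#' @export
composite_score <- function(annotation) {
  stopifnot(inherits(annotation, "druggability_annotation"))
  sum(annotation$has_ligand_bound_structure,
      annotation$structure_druggable_or_tractable,
      annotation$ligand_druggability_percentile >= 90,
      annotation$has_ec_number,
      annotation$visual_pocket_score >= 3L,
      annotation$charge_altering,
      annotation$introduces_cysteine)
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' Computes `sum((|O - E| - 0.5)^2 / E)` with expected counts from the
#' marginal products and one degree of freedom; the correction is clamped
#' so `|O - E| - 0.5` never goes negative. Cross-checked against
#' `stats::chisq.test(correct = TRUE)`, which applies the same clamped
#' correction.
#'
#' @param table A 2x2 matrix of counts.
#' @return A list with `statistic` and `p`.
#' @export
yates_chi_square <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2L, ncol(table) == 2L, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in 2x2 table")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((pmax(abs(table - E) - 0.5, 0))^2 / E)
  list(statistic = stat, p = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Assemble the target compendium
#'
#' Joins the common-variant catalog to the final essential-gene set (one
#' row per variant in an essential gene), attaching heterozygosity, LOH
#' rates (pan-cancer and per tumor type; 0 when a gene was called but never
#' observed in LOH — LOH rate annotates, it does not gate membership),
#' patient-reach estimates, allele-specific PAM status, DEMETER2 dependency
#' class, and the druggability composite. Rows are ordered by gene then
#' position. Variants whose gene has no LOH rate row (gene absent from the
#' copy-number data) are emitted with missing LOH annotation and a warning.
#'
#' @param essential_calls Output of [run_cascade()] (or any data.frame with
#'   `gene_symbol` and `final_essential`).
#' @param catalog Filtered variant catalog ([filter_common_variants()]).
#' @param loh_rates Pan-cancer rate table from [cohort_gene_loh_rate()].
#' @param loh_rates_by_type Optional per-type rate table.
#' @param guides Optional guide table from [design_guides()].
#' @param demeter2 Optional DEMETER2 matrix (genes x cell lines).
#' @param annotations Optional named list of [druggability_annotation()]
#'   keyed by `variant_id`.
#' @param kappa Annual incidence for [patients_per_year()].
#' @return A compendium data.frame (see [compendium_columns()]); per-type
#'   LOH rates appear as `loh_rate_<type>` columns.
#' @export
assemble_compendium <- function(essential_calls, catalog, loh_rates,
                                loh_rates_by_type = NULL, guides = NULL,
                                demeter2 = NULL, annotations = NULL,
                                kappa = 1735350) {
  essential <- essential_calls$gene_symbol[essential_calls$final_essential]
  rows <- catalog[catalog$gene_symbol %in% essential, , drop = FALSE]
  if (nrow(rows) == 0L) {
    out <- empty_variant_frame()
    for (cn in setdiff(compendium_columns(), names(out))) out[[cn]] <- numeric()
    return(out[, compendium_columns(), drop = FALSE])
  }
  rows <- rows[order(rows$gene_symbol, rows$position), , drop = FALSE]
  rownames(rows) <- NULL

  rate_of <- stats::setNames(loh_rates$rate, loh_rates$gene_symbol)
  rows$heterozygosity <- heterozygosity(rows$maf)
  rows$loh_rate_pan <- unname(rate_of[rows$gene_symbol])
  if (any(is.na(rows$loh_rate_pan)))
    warning(sum(is.na(rows$loh_rate_pan)),
            " variant(s) reference genes without LOH calls; ",
            "emitted without LOH annotation")
  rows$patients_per_year <- ifelse(
    is.na(rows$loh_rate_pan), NA_real_,
    patients_per_year(kappa, rows$heterozygosity,
                      ifelse(is.na(rows$loh_rate_pan), 0, rows$loh_rate_pan)))

  specific_ids <- if (is.null(guides)) character() else unique(guides$variant_id)
  rows$pam_allele_specific <- rows$variant_id %in% specific_ids

  rows$demeter2_median <- NA_real_
  rows$strong_dependency <- NA
  if (!is.null(demeter2)) {
    for (g in unique(rows$gene_symbol)) {
      if (g %in% rownames(demeter2)) {
        dep <- classify_dependency(demeter2[g, ])
        sel <- rows$gene_symbol == g
        rows$demeter2_median[sel] <- dep$median
        rows$strong_dependency[sel] <- dep$strong
      }
    }
  }

  rows$composite_score <- NA_integer_
  if (!is.null(annotations)) {
    hit <- rows$variant_id %in% names(annotations)
    rows$composite_score[hit] <- vapply(
      annotations[rows$variant_id[hit]], composite_score, integer(1))
  }

  if (!is.null(loh_rates_by_type)) {
    for (ty in sort(unique(loh_rates_by_type$stratum))) {
      sub <- loh_rates_by_type[loh_rates_by_type$stratum == ty, ]
      m <- stats::setNames(sub$rate, sub$gene_symbol)
      rows[[paste0("loh_rate_", ty)]] <- unname(m[rows$gene_symbol])
    }
  }
  rows[, c(compendium_columns(),
           setdiff(names(rows), compendium_columns())), drop = FALSE]
}
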