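# Common-variant catalog: filtering, Hardy-Weinberg heterozygosity,
# per-gene summaries, MAF comparisons, and protein-level sequence utilities.

#' Filter a variant table down to the common-variant catalog
#'
#' Retains variants that PASS upstream filters, whose minor allele frequency
#' is at least `maf_min` (inclusive: a variant at exactly the threshold is
#' kept), and whose consequence class belongs to the admitted set. Input
#' order is preserved and the operation is idempotent.
#'
#' @param variants Variant data.frame from [read_variants()].
#' @param maf_min Minimum minor allele frequency; default 0.01 ("common").
#' @param classes Admitted consequence classes; default [consequence_classes()].
#' @return The retained rows of `variants`.
#' @export
filter_common_variants <- function(variants, maf_min = 0.01,
                                   classes = consequence_classes()) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  keep <- variants$filter_status == "PASS" &
    !is.na(variants$maf) & variants$maf >= maf_min &
    variants$consequence_class %in% classes
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expected heterozygote fraction under Hardy-Weinberg
#'
#' For a biallelic locus with minor allele frequency `p`, the expected
#' fraction of heterozygous individuals is `2 p (1 - p)` (the 2pq term of
#' the Hardy-Weinberg expansion). Frequencies must already be folded to the
#' minor allele, so values above 0.5 are rejected rather than silently
#' reinterpreted.
#'
#' @param maf Minor allele frequency (vectorized), each in \[0, 0.5\].
#' @return Expected heterozygosity, same length as `maf`.
#' @examples
#' heterozygosity(0.177)  # ~0.291, i.e. 29% of individuals heterozygous
#' @export
heterozygosity <- function(maf) {
  if (any(is.na(maf)) || any(maf < 0) || any(maf > 0.5))
    stop("maf must lie in [0, 0.5]; fold alternate-allele frequencies first")
  2 * maf * (1 - maf)
}

#' Per-gene variant counts and cohort medians
#'
#' @param variants Filtered catalog data.frame.
#' @return A list with `per_gene` (data.frame: `gene_symbol`, `n_variants`,
#'   `median_maf`) and cohort scalars `median_variants_per_gene` and
#'   `median_maf` (both `NA` for an empty catalog).
#' @export
per_gene_variant_summary <- function(variants) {
  if (nrow(variants) == 0L) {
    return(list(per_gene = data.frame(gene_symbol = character(),
                                      n_variants = integer(),
                                      median_maf = numeric()),
                median_variants_per_gene = NA_real_,
                median_maf = NA_real_))
  }
  dt <- data.table::as.data.table(variants)
  per_gene <- dt[, list(n_variants = .N, median_maf = stats::median(maf)),
                 by = "gene_symbol"]
  data.table::setorderv(per_gene, "gene_symbol")
  list(per_gene = data.table::setDF(per_gene),
       median_variants_per_gene = stats::median(per_gene$n_variants),
       median_maf = stats::median(variants$maf))
}

#' One-sided Welch t-test comparing MAF distributions
#'
#' Tests whether variants in essential genes have lower minor allele
#' frequencies than those in non-essential genes (alternative:
#' essential < non-essential), using the unequal-variance Welch statistic.
#'
#' @param essential_mafs,nonessential_mafs Numeric vectors, length >= 2 each.
#' @return A list with `t` and one-sided `p`.
#' @export
compare_maf_distributions <- function(essential_mafs, nonessential_mafs) {
  if (length(essential_mafs) < 2L || length(nonessential_mafs) < 2L)
    stop("need at least two values per group")
  if (stats::var(essential_mafs) == 0 && stats::var(nonessential_mafs) == 0)
    stop("degenerate input: both groups have zero variance")
  ht <- stats::t.test(essential_mafs, nonessential_mafs,
                      alternative = "less", var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Translate a DNA context in all six reading frames
#'
#' Three forward frames and three frames of the reverse complement, using
#' the standard codon table; trailing partial codons are dropped and stop
#' codons render as `*`.
#'
#' @param context DNA string over ACGT, length >= 3 (typically the 30-mer
#'   around a protein-altering variant).
#' @return Character vector of six peptides, named `F0`,`F1`,`F2`,
#'   `R0`,`R1`,`R2`.
#' @export
six_frame_translate <- function(context) {
  context <- toupper(context)
  if (!grepl("^[ACGT]+$", context)) stop("context must be over A/C/G/T")
  if (nchar(context) < 3L) stop("context shorter than one codon")
  fwd <- Biostrings::DNAString(context)
  rev <- Biostrings::reverseComplement(fwd)
  frame_of <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + n),
                                       no.init.codon = TRUE))
  }
  c(F0 = frame_of(fwd, 0L), F1 = frame_of(fwd, 1L), F2 = frame_of(fwd, 2L),
    R0 = frame_of(rev, 0L), R1 = frame_of(rev, 1L), R2 = frame_of(rev, 2L))
}

#' Classify a protein-level change
#'
#' Kind is assigned by comparing residue-string lengths: equal lengths of 1
#' are missense, a longer alternate is an in-frame insertion, a shorter one
#' an in-frame deletion, and equal multi-residue lengths are `other`.
#' Synonymous input (identical residue strings) is a classification error:
#' it is not protein-altering.
#'
#' @param ref_residues,alt_residues Amino-acid strings (one-letter code,
#'   `*` allowed for stop).
#' @param position 1-based residue position of the change.
#' @return A list of class `protein_change` with `kind`, `ref_residues`,
#'   `alt_residues`, `residue_position` and an HGVS-like `label` (e.g. `D5A`).
#' @export
classify_protein_change <- function(ref_residues, alt_residues, position) {
  aa <- "^[ACDEFGHIKLMNPQRSTVWY*]+$"
  if (!grepl(aa, ref_residues) || !grepl(aa, alt_residues))
    stop("residues must use the 20-letter amino-acid alphabet plus '*'")
  if (identical(ref_residues, alt_residues))
    stop("classification error: identical residue strings are synonymous")
  nr <- nchar(ref_residues); na <- nchar(alt_residues)
  kind <- if (nr == 1L && na == 1L) "missense"
          else if (na > nr) "inframe_insertion"
          else if (na < nr) "inframe_deletion"
          else "other"
  structure(list(kind = kind, ref_residues = ref_residues,
                 alt_residues = alt_residues,
                 residue_position = as.integer(position),
                 label = paste0(ref_residues, position, alt_residues)),
            class = "protein_change")
}

#' @export
print.protein_change <- function(x, ...) {
  cat("<protein_change>", x$label, "(", x$kind, ")\n")
  invisible(x)
}
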