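# Loss-of-heterozygosity calling: per-gene transformation of allelic
# segments and cohort-level LOH statistics.

#' Classify the LOH state of a gene-level allelic call
#'
#' A locus has undergone LOH when the absolute copy number of one allele is
#' zero, restricted to autosomes. LOH events split on the gene-level
#' relative copy number: `copy_loss` when log2 relative <= `log2_loss_cut`
#' (boundary inclusive) and `copy_neutral` above it.
#'
#' @param minor_cn Integer minor allelic copy number (vectorized).
#' @param log2_relative Gene-level log2 relative total copy number.
#' @param is_autosome Logical; sex-chromosome loci are never called LOH.
#' @param log2_loss_cut Copy-loss threshold, default -0.1.
#' @return Character vector: `"none"`, `"copy_loss"` or `"copy_neutral"`.
#' @export
classify_loh <- function(minor_cn, log2_relative, is_autosome,
                         log2_loss_cut = -0.1) {
  if (any(minor_cn < 0, na.rm = TRUE)) stop("negative minor_cn")
  out <- rep("none", length(minor_cn))
  loh <- !is.na(minor_cn) & minor_cn == 0L & is_autosome
  out[loh & log2_relative <= log2_loss_cut] <- "copy_loss"
  out[loh & log2_relative > log2_loss_cut] <- "copy_neutral"
  out
}

#' Transform allelic segments into per-gene LOH calls
#'
#' For every (sample, gene) pair, the overlapping segment with the greatest
#' overlap length supplies the gene's allelic copy numbers; ties break to
#' the segment with the leftmost start. Genes with no overlapping segment in
#' a sample are missing for that sample (they are excluded from rate
#' denominators, not counted as non-LOH). Contradictory overlapping
#' segments are resolved by the same rule and flagged with a warning.
#'
#' @param segments Segment data.frame from [read_allelic_segments()].
#' @param genes Gene-model data.frame from [read_gene_bed()].
#' @param log2_loss_cut Copy-loss threshold passed to [classify_loh()].
#' @return A data.frame with one row per (sample, gene) pair that received a
#'   call: `sample_id`, `tumor_type`, `gene_symbol`, `minor_cn`,
#'   `log2_relative`, `loh_class`.
#' @export
segments_to_gene_calls <- function(segments, genes, log2_loss_cut = -0.1) {
  validate_segments(segments)
  if (nrow(genes) == 0L) stop("no gene models supplied")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end))
  seg_gr <- GenomicRanges::GRanges(
    seqnames = segments$chromosome,
    ranges = IRanges::IRanges(start = segments$start + 1L,
                              end = segments$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (length(hits) == 0L) {
    return(data.frame(sample_id = character(), tumor_type = character(),
                      gene_symbol = character(), minor_cn = integer(),
                      log2_relative = numeric(), loh_class = character(),
                      stringsAsFactors = FALSE))
  }
  gi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(GenomicRanges::pintersect(gene_gr[gi], seg_gr[si]))
  dt <- data.table::data.table(
    gene_symbol = genes$gene_symbol[gi],
    is_autosome = genes$is_autosome[gi],
    sample_id = segments$sample_id[si],
    tumor_type = segments$tumor_type[si],
    seg_start = segments$start[si],
    minor_cn = segments$minor_cn[si],
    log2_relative = segments$log2_relative[si],
    overlap = ov
  )
  # max overlap wins; ties go to the leftmost segment start
  data.table::setorderv(dt, c("sample_id", "gene_symbol", "overlap",
                              "seg_start"), order = c(1L, 1L, -1L, 1L))
  n_hits <- dt[, list(n = .N, n_classes = length(unique(minor_cn == 0L))),
               by = c("sample_id", "gene_symbol")]
  if (any(n_hits$n_classes > 1L))
    warning(sum(n_hits$n_classes > 1L),
            " (sample, gene) pair(s) spanned segments with contradictory ",
            "LOH state; resolved by maximal overlap")
  best <- dt[, utils::head(.SD, 1L), by = c("sample_id", "gene_symbol")]
  best[, "loh_class" := classify_loh(best$minor_cn, best$log2_relative,
                                     best$is_autosome, log2_loss_cut)]
  out <- data.table::setDF(best[, c("sample_id", "tumor_type", "gene_symbol",
                                    "minor_cn", "log2_relative",
                                    "loh_class"), with = FALSE])
  data.table::setorderv(data.table::setDT(out), c("sample_id", "gene_symbol"))
  data.table::setDF(out)
}

#' Fraction of a sample's callable genes that underwent LOH
#'
#' @param calls Gene-call data.frame for one sample.
#' @return Fraction of called genes with `loh_class != "none"`, or `NA`
#'   when the sample has no callable genes.
#' @export
sample_loh_fraction <- function(calls) {
  if (nrow(calls) == 0L) return(NA_real_)
  mean(calls$loh_class != "none")
}

#' Number of essential genes affected by LOH in one sample
#'
#' @param calls Gene-call data.frame for one sample.
#' @param essential_set Character vector of essential gene symbols.
#' @return Integer count.
#' @export
sample_essential_loh_count <- function(calls, essential_set) {
  sum(calls$gene_symbol %in% essential_set & calls$loh_class != "none")
}

#' Per-gene LOH rates across a cohort
#'
#' Rates are computed per gene over samples with a call: the LOH rate is
#' the fraction of called samples with any LOH, and the copy-neutral share
#' is the fraction of LOH events that are copy-neutral.
#'
#' @param calls Gene-call data.frame from [segments_to_gene_calls()].
#' @param by `"pan_cancer"` for one stratum, `"tumor_type"` for per-type rates.
#' @return A data.frame with columns `gene_symbol`, `stratum`, `n_called`,
#'   `n_loh`, `n_copy_neutral`, `rate`, `copy_neutral_share`.
#' @export
cohort_gene_loh_rate <- function(calls, by = c("pan_cancer", "tumor_type")) {
  by <- match.arg(by)
  dt <- data.table::as.data.table(calls)
  dt[, "stratum" := if (by == "pan_cancer") "pan_cancer" else dt$tumor_type]
  rates <- dt[, list(
    n_called = .N,
    n_loh = sum(loh_class != "none"),
    n_copy_neutral = sum(loh_class == "copy_neutral")
  ), by = c("gene_symbol", "stratum")]
  rates[, "rate" := rates$n_loh / rates$n_called]
  rates[, "copy_neutral_share" := ifelse(rates$n_loh > 0L,
                                         rates$n_copy_neutral / rates$n_loh,
                                         NA_real_)]
  data.table::setorderv(rates, c("gene_symbol", "stratum"))
  data.table::setDF(rates)
}

#' One-sided Welch t-test comparing per-gene LOH rates
#'
#' Alternative hypothesis: essential genes have lower LOH rates than
#' non-essential genes.
#'
#' @param essential_rates,nonessential_rates Per-gene pan-cancer LOH rates.
#' @return A list with `t` and one-sided `p`.
#' @export
compare_loh_rates <- function(essential_rates, nonessential_rates) {
  compare_maf_distributions(essential_rates, nonessential_rates)
}

#' Write per-gene LOH rates to TSV
#'
#' @param rates Output of [cohort_gene_loh_rate()].
#' @param path Output path.
#' @export
write_loh_rates <- function(rates, path) {
  data.table::fwrite(rates, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
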