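# Essential-gene nomination and the filter cascade: haploid-screen FDR,
# gene-trap binomial model, CCLE exclusion rules, CERES dependency filter,
# missing-data rescue, and tumor-suppressor removal.

#' Gene-trap orientation FDR
#'
#' In haploid insertional mutagenesis, sense-orientation (disruptive)
#' insertions are depleted in essential genes while a null gene receives
#' sense and antisense insertions with equal probability. Each gene's
#' p-value is the lower-tail exact binomial probability
#' `P(X <= sense | n, 0.5)` with `n = sense + antisense` (the one-sided
#' sense-depletion tail), and q-values are Benjamini-Hochberg adjusted
#' across all tested genes. Genes with no insertions are untested and
#' receive `NA`.
#'
#' @param sense,antisense Non-negative integer insertion counts per gene.
#' @return A data.frame with columns `sense`, `antisense`, `p`, `q`.
#' @export
gene_trap_fdr <- function(sense, antisense) {
  if (length(sense) != length(antisense))
    stop("sense and antisense must have equal length")
  if (any(sense < 0, na.rm = TRUE) || any(antisense < 0, na.rm = TRUE))
    stop("validation error: negative gene-trap counts")
  n <- sense + antisense
  p <- ifelse(n >= 1L, stats::pbinom(sense, n, 0.5), NA_real_)
  q <- rep(NA_real_, length(p))
  tested <- !is.na(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  data.frame(sense = sense, antisense = antisense, p = p, q = q)
}

#' Nominate candidate essential genes from three haploid screens
#'
#' A gene is a candidate when its FDR q-value falls strictly below the
#' threshold in at least one of the three screens.
#'
#' @param q_matrix Numeric matrix, genes x 3 screens, of FDR q-values
#'   (`NA` = untested in that screen).
#' @param fdr Threshold, default 0.10; strict inequality.
#' @return A data.frame with `candidate` (logical) and `n_screens_passed`.
#' @export
nominate_candidates <- function(q_matrix, fdr = 0.10) {
  stopifnot(is.matrix(q_matrix), ncol(q_matrix) == 3L, fdr > 0, fdr < 1)
  passed <- !is.na(q_matrix) & q_matrix < fdr
  n_passed <- rowSums(passed)
  data.frame(gene_symbol = rownames(q_matrix) %||% as.character(seq_len(nrow(q_matrix))),
             candidate = n_passed >= 1L,
             n_screens_passed = as.integer(n_passed),
             stringsAsFactors = FALSE)
}

#' CCLE loss-of-function exclusion filter
#'
#' Excludes a candidate gene when cell-line data show it tolerates loss of
#' function: homozygously deleted (log2 copy number < -5) in more than two
#' cell lines; expressed below 0.5 RPKM in more than five cell lines; or
#' homozygously deleted in at least one cell line that in the same line is
#' expressed below 1.0 RPKM. When both CCLE vectors are absent the filter
#' is inapplicable and the gene is not excluded (reason `"missing_data"`).
#'
#' @param log2_cn Per-cell-line log2 copy numbers (or `NULL`/all-`NA`).
#' @param rpkm Per-cell-line RNA expression in RPKM (or `NULL`/all-`NA`).
#' @return A list with `excluded` (logical) and `reason` (one of
#'   `"homdel_multi"`, `"low_expression"`, `"homdel_low_expr"`,
#'   `"missing_data"`, `"none"`).
#' @export
ccle_filter <- function(log2_cn, rpkm) {
  has_cn <- !is.null(log2_cn) && any(!is.na(log2_cn))
  has_expr <- !is.null(rpkm) && any(!is.na(rpkm))
  if (!has_cn && !has_expr)
    return(list(excluded = FALSE, reason = "missing_data"))
  if (has_cn && sum(log2_cn < -5, na.rm = TRUE) > 2L)
    return(list(excluded = TRUE, reason = "homdel_multi"))
  if (has_expr && sum(rpkm < 0.5, na.rm = TRUE) > 5L)
    return(list(excluded = TRUE, reason = "low_expression"))
  if (has_cn && has_expr) {
    both <- !is.na(log2_cn) & !is.na(rpkm) & log2_cn < -5 & rpkm < 1.0
    if (sum(both) >= 1L)
      return(list(excluded = TRUE, reason = "homdel_low_expr"))
  }
  list(excluded = FALSE, reason = "none")
}

#' CERES dependency filter
#'
#' A candidate is excluded when its mean CERES score over non-missing cell
#' lines exceeds -0.4 (insufficient dependency); a mean of exactly -0.4 is
#' retained.
#'
#' @param ceres_scores Per-cell-line CERES scores.
#' @param ceres_cut Threshold, default -0.4.
#' @return Logical; `NA` when no CERES data exist.
#' @export
ceres_filter <- function(ceres_scores, ceres_cut = -0.4) {
  if (is.null(ceres_scores) || all(is.na(ceres_scores))) return(NA)
  mean(ceres_scores, na.rm = TRUE) > ceres_cut
}

#' Rescue rule for genes lacking CCLE data
#'
#' Genes whose CCLE copy-number and expression data are unavailable cannot
#' be cleared by the CCLE filter; they are rescued when they scored as
#' essential in at least two of the three haploid screens and their mean
#' CERES score is below -0.4 (strict).
#'
#' @param ccle_missing Logical; CCLE data absent for the gene.
#' @param n_screens_passed Integer 0-3.
#' @param ceres_scores Per-cell-line CERES scores.
#' @param ceres_cut Threshold, default -0.4.
#' @return Logical.
#' @export
rescue_rule <- function(ccle_missing, n_screens_passed, ceres_scores,
                        ceres_cut = -0.4) {
  if (!ccle_missing) return(FALSE)
  if (is.null(ceres_scores) || all(is.na(ceres_scores))) return(FALSE)
  n_screens_passed >= 2L && mean(ceres_scores, na.rm = TRUE) < ceres_cut
}

#' Run the full essential-gene filter cascade
#'
#' Orders the stages as: three-screen nomination; CCLE loss-of-function
#' exclusion; CERES dependency exclusion; rescue of CCLE-missing genes that
#' passed two screens with mean CERES < -0.4 (a rescued gene waives the
#' CERES exclusion, which its rescue condition already implies); removal of
#' Tier 1 tumor suppressor genes; and restriction to genes characterized in
#' the tumor copy-number data.
#'
#' @param evidence An `essentiality_evidence` list as built by
#'   [simulate_screens()] or assembled from matrices: elements `crispr_q`
#'   (genes x 2 matrix), `gene_trap` (genes x 2 matrix, columns
#'   sense/antisense), `ccle_log2_cn`, `ccle_rpkm`, `ceres` (genes x lines
#'   matrices; `NA` rows = missing).
#' @param tsg_list Character vector of Tier 1 tumor-suppressor symbols.
#' @param genes_with_cn_calls Character vector of genes present in the tumor
#'   copy-number/LOH data; `NULL` skips the restriction.
#' @param fdr Screen FDR threshold, default 0.10.
#' @param ceres_cut CERES threshold, default -0.4.
#' @return A data.frame with one row per gene: `gene_symbol`, `candidate`,
#'   `n_screens_passed`, `ccle_excluded`, `ccle_reason`, `ceres_excluded`,
#'   `rescued`, `tsg_excluded`, `no_cn_call`, `final_essential`, plus a
#'   `stage_counts` attribute logging the per-stage accounting.
#' @export
run_cascade <- function(evidence, tsg_list = character(),
                        genes_with_cn_calls = NULL, fdr = 0.10,
                        ceres_cut = -0.4) {
  genes <- rownames(evidence$crispr_q)
  if (is.null(genes)) stop("evidence$crispr_q must have gene rownames")
  gt <- gene_trap_fdr(evidence$gene_trap[, "sense"],
                      evidence$gene_trap[, "antisense"])
  q_matrix <- cbind(evidence$crispr_q, gene_trap = gt$q)
  rownames(q_matrix) <- genes
  nom <- nominate_candidates(q_matrix, fdr = fdr)

  n <- length(genes)
  ccle_excluded <- logical(n); ccle_reason <- character(n)
  ceres_excluded <- logical(n); rescued <- logical(n)
  for (i in seq_len(n)) {
    cn <- evidence$ccle_log2_cn[i, ]
    expr <- evidence$ccle_rpkm[i, ]
    ces <- evidence$ceres[i, ]
    cf <- ccle_filter(cn, expr)
    ccle_excluded[i] <- cf$excluded
    ccle_reason[i] <- cf$reason
    ce <- ceres_filter(ces, ceres_cut)
    ceres_excluded[i] <- isTRUE(ce)
    rescued[i] <- rescue_rule(cf$reason == "missing_data",
                              nom$n_screens_passed[i], ces, ceres_cut)
  }
  tsg_excluded <- genes %in% tsg_list
  no_cn_call <- if (is.null(genes_with_cn_calls)) rep(FALSE, n)
                else !(genes %in% genes_with_cn_calls)

  # A gene with missing CCLE data is not excluded by the CCLE filter, but
  # without rescue it still needs to clear the CERES filter; a rescued gene
  # has mean CERES < cut by construction.
  final <- nom$candidate &
    (!ccle_excluded | rescued) &
    (!ceres_excluded | rescued) &
    !tsg_excluded & !no_cn_call

  out <- data.frame(gene_symbol = genes,
                    candidate = nom$candidate,
                    n_screens_passed = nom$n_screens_passed,
                    ccle_excluded = ccle_excluded,
                    ccle_reason = ccle_reason,
                    ceres_excluded = ceres_excluded,
                    rescued = rescued,
                    tsg_excluded = tsg_excluded,
                    no_cn_call = no_cn_call,
                    final_essential = final,
                    stringsAsFactors = FALSE)
  attr(out, "stage_counts") <- c(
    tested = n,
    candidates = sum(nom$candidate),
    after_ccle = sum(nom$candidate & !ccle_excluded),
    after_ceres = sum(nom$candidate & !ccle_excluded & !ceres_excluded),
    rescued = sum(rescued & nom$candidate),
    after_tsg = sum(nom$candidate & (!ccle_excluded | rescued) &
                      (!ceres_excluded | rescued) & !tsg_excluded),
    final = sum(final)
  )
  out
}
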