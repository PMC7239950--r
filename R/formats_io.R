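# Readers and writers for the external formats the pipeline touches.
# All readers emit plain data.frames with a documented column contract and
# 0-based half-open internal coordinates.

#' Read a germline variant table (VCF subset or TSV)
#'
#' Variants are read from either a VCF 4.x subset (CHROM, POS, ID, REF, ALT,
#' FILTER, INFO with an `AF` and a consequence tag `CSQ`, and a `GENE` tag)
#' or from a TSV with header columns `variant_id`, `gene_symbol`,
#' `chromosome`, `position` (1-based), `ref_allele`, `alt_allele`,
#' `consequence_class`, `global_af`, `filter_status`.
#'
#' Positions are normalized to 0-based; chromosome labels lose any leading
#' `"chr"`. The alternate-allele frequency is folded to a minor allele
#' frequency: values above 0.5 are reported as `1 - AF`, so all downstream
#' arithmetic sees MAF. Rows with unparsable alleles (characters outside
#' ACGT) are skipped with a warning naming the offending line.
#'
#' @param path Path to the variant file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return A data.frame with columns `variant_id`, `gene_symbol`,
#'   `chromosome`, `position` (0-based), `ref_allele`, `alt_allele`,
#'   `consequence_class`, `maf`, `filter_status`.
#' @export
read_variants <- function(path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("variant file does not exist: ", path)
  if (dialect == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcf@fix
    if (nrow(fix) == 0L) return(empty_variant_frame())
    af <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = "AF")))
    csq <- vcfR::extract.info(vcf, element = "CSQ")
    gene <- vcfR::extract.info(vcf, element = "GENE")
    if (all(is.na(af))) stop("variant format error: missing INFO field AF")
    if (all(is.na(csq))) stop("variant format error: missing INFO field CSQ")
    d <- data.frame(
      variant_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                          paste0("var_", seq_len(nrow(fix))), fix[, "ID"]),
      gene_symbol = if (all(is.na(gene))) NA_character_ else gene,
      chromosome = normalize_chrom(fix[, "CHROM"]),
      position = as.integer(fix[, "POS"]) - 1L,
      ref_allele = fix[, "REF"],
      alt_allele = fix[, "ALT"],
      consequence_class = csq,
      maf = af,
      filter_status = ifelse(fix[, "FILTER"] == "PASS", "PASS", "other"),
      stringsAsFactors = FALSE
    )
  } else {
    d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
    required <- c("variant_id", "gene_symbol", "chromosome", "position",
                  "ref_allele", "alt_allele", "consequence_class",
                  "global_af", "filter_status")
    missing_cols <- setdiff(required, names(d))
    if (length(missing_cols) > 0L)
      stop("variant format error: missing column(s) ",
           paste(missing_cols, collapse = ", "))
    if (nrow(d) == 0L) return(empty_variant_frame())
    d <- data.frame(
      variant_id = as.character(d$variant_id),
      gene_symbol = as.character(d$gene_symbol),
      chromosome = normalize_chrom(d$chromosome),
      position = as.integer(d$position) - 1L,
      ref_allele = as.character(d$ref_allele),
      alt_allele = as.character(d$alt_allele),
      consequence_class = as.character(d$consequence_class),
      maf = as.numeric(d$global_af),
      filter_status = ifelse(d$filter_status == "PASS", "PASS", "other"),
      stringsAsFactors = FALSE
    )
  }
  bad_allele <- !grepl("^[ACGT]+$", d$ref_allele) |
    !grepl("^[ACGT]+$", d$alt_allele) | d$ref_allele == d$alt_allele
  bad_af <- is.na(d$maf) | d$maf < 0 | d$maf > 1
  bad <- bad_allele | bad_af
  if (any(bad)) {
    warning(sum(bad), " malformed variant row(s) skipped (rows: ",
            paste(utils::head(which(bad), 10L), collapse = ", "), ")")
    d <- d[!bad, , drop = FALSE]
  }
  # fold alternate-allele frequency to minor allele frequency
  d$maf <- ifelse(d$maf > 0.5, 1 - d$maf, d$maf)
  rownames(d) <- NULL
  d
}

empty_variant_frame <- function() {
  data.frame(variant_id = character(), gene_symbol = character(),
             chromosome = character(), position = integer(),
             ref_allele = character(), alt_allele = character(),
             consequence_class = character(), maf = numeric(),
             filter_status = character(), stringsAsFactors = FALSE)
}

#' Read per-sample allelic copy-number segments
#'
#' Reads a purity/ploidy-corrected allelic segment table (one row per
#' sample-segment, in the style of pan-cancer ABSOLUTE master calls) with
#' columns `sample`, `tumor_type`, `chromosome`, `start`, `end` (1-based
#' inclusive), `major_cn`, `minor_cn` (integer absolute allelic copies) and
#' `log2_relative` (gene-level relative total copy number on the log2 scale).
#'
#' @param path Path to the TSV.
#' @return A data.frame with columns `sample_id`, `tumor_type`, `chromosome`,
#'   `start`, `end` (0-based half-open), `major_cn`, `minor_cn`,
#'   `log2_relative`.
#' @export
read_allelic_segments <- function(path) {
  if (!file.exists(path)) stop("segment file does not exist: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  required <- c("sample", "tumor_type", "chromosome", "start", "end",
                "major_cn", "minor_cn", "log2_relative")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0L)
    stop("segment format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(
    sample_id = as.character(d$sample),
    tumor_type = as.character(d$tumor_type),
    chromosome = normalize_chrom(d$chromosome),
    start = as.integer(d$start) - 1L,   # 1-based inclusive -> 0-based half-open
    end = as.integer(d$end),
    major_cn = as.integer(d$major_cn),
    minor_cn = as.integer(d$minor_cn),
    log2_relative = as.numeric(d$log2_relative),
    stringsAsFactors = FALSE
  )
  validate_segments(out)
  out
}

validate_segments <- function(seg) {
  if (any(seg$minor_cn < 0 | seg$major_cn < 0)) {
    i <- which(seg$minor_cn < 0 | seg$major_cn < 0)[1L]
    stop("segment validation error: negative copy number for sample ",
         seg$sample_id[i], " at ", seg$chromosome[i], ":", seg$start[i], "-",
         seg$end[i])
  }
  if (any(seg$minor_cn > seg$major_cn)) {
    i <- which(seg$minor_cn > seg$major_cn)[1L]
    stop("segment validation error: minor_cn > major_cn for sample ",
         seg$sample_id[i], " at ", seg$chromosome[i], ":", seg$start[i], "-",
         seg$end[i])
  }
  if (any(seg$start >= seg$end))
    stop("segment validation error: empty or inverted interval")
  invisible(seg)
}

#' Read gene models from a BED4 file
#'
#' Standard BED is already 0-based half-open, which matches the internal
#' convention, so coordinates pass through unchanged.
#'
#' @param path Path to a BED4 file (chrom, start, end, gene symbol).
#' @return A data.frame with columns `gene_symbol`, `chromosome`, `start`,
#'   `end`, `is_autosome`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("BED file does not exist: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chromosome", "start", "end",
                                       "gene_symbol"),
                         colClasses = c("character", "integer", "integer",
                                       "character"))
  dup <- unique(d$gene_symbol[duplicated(d$gene_symbol)])
  if (length(dup) > 0L)
    stop("duplicated gene symbols in BED: ", paste(dup, collapse = ", "))
  out <- data.frame(
    gene_symbol = d$gene_symbol,
    chromosome = normalize_chrom(d$chromosome),
    start = d$start,
    end = d$end,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) stop("BED validation error: start >= end")
  out$is_autosome <- is_autosome_label(out$chromosome)
  out
}

#' Read variant context sequences from FASTA
#'
#' @param path Path to a FASTA file keyed by variant (or gene) id.
#' @return A named character vector of upper-case DNA sequences.
#' @export
read_fasta_contexts <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(ss)), names(ss))
}

#' Write context sequences to FASTA
#'
#' @param contexts Named character vector of DNA sequences.
#' @param path Output path.
#' @export
write_fasta_contexts <- function(contexts, path) {
  ss <- Biostrings::DNAStringSet(contexts)
  names(ss) <- names(contexts)
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a gene-by-cell-line numeric matrix from CSV
#'
#' First column holds gene symbols; remaining columns are cell lines.
#' Empty cells become `NA`, never zero.
#'
#' @param path Path to the CSV.
#' @return A numeric matrix with gene rownames and cell-line colnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file does not exist: ", path)
  d <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                       na.strings = c("", "NA")))
  if (ncol(d) < 2L) stop("matrix format error: need gene column plus data")
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(d[[1L]])
  m
}

#' Write a gene-by-cell-line matrix to CSV
#'
#' @param m Numeric matrix with gene rownames.
#' @param path Output path.
#' @param gene_col Name for the leading gene-symbol column.
#' @export
write_matrix <- function(m, path, gene_col = "gene_symbol") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- gene_col
  data.table::fwrite(d, path, sep = ",", na = "NA", quote = FALSE)
  invisible(path)
}

# Fixed column order of the compendium TSV; write_compendium() and
# read_compendium() round-trip this contract losslessly.
compendium_columns <- function() {
  c("variant_id", "gene_symbol", "chromosome", "position", "ref_allele",
    "alt_allele", "consequence_class", "maf", "heterozygosity",
    "loh_rate_pan", "patients_per_year", "pam_allele_specific",
    "demeter2_median", "strong_dependency", "composite_score")
}

#' Write the target compendium to TSV
#'
#' One row per (common variant, essential gene) pair with the fixed column
#' order given by `compendium_columns()`; extra columns (for example
#' per-tumor-type LOH rates) are appended after the fixed block. Values are
#' written at full precision so a write/read cycle is lossless.
#'
#' @param targets Compendium data.frame from [assemble_compendium()].
#' @param path Output TSV path.
#' @export
write_compendium <- function(targets, path) {
  fixed <- compendium_columns()
  missing_cols <- setdiff(fixed, names(targets))
  if (length(missing_cols) > 0L)
    stop("compendium is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(targets), fixed)
  out <- targets[, c(fixed, extra), drop = FALSE]
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_compendium
#' @export
read_compendium <- function(path) {
  if (!file.exists(path)) stop("compendium file does not exist: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                       na.strings = "NA",
                                       colClasses = list(character = "chromosome")))
  missing_cols <- setdiff(compendium_columns(), names(d))
  if (length(missing_cols) > 0L)
    stop("compendium format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  d$chromosome <- as.character(d$chromosome)
  d
}
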