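# Allele-specific Cas9 PAM discovery and guide design.
#
# A variant is allele-specifically targetable when one allele carries a
# S. pyogenes PAM (canonical NGG or the weaker non-canonical NAG) at a
# placement where the other allele carries none: the PAM-bearing
# ("sensitive") allele is cleavable by a guide whose 20-nt protospacer lies
# immediately 5' of the PAM, while the PAM-less ("resistant") allele is not.

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

#' Build an allele context around a variant
#'
#' @param variant_id Identifier.
#' @param window DNA string (default design uses 61 nt: 30-nt flanks around
#'   the variant, wide enough for a 20-nt protospacer + PAM on either side).
#' @param variant_offset 0-based offset of the first variant base in
#'   `window`.
#' @param ref_allele,alt_allele Allele strings over ACGT; the window must
#'   carry the reference allele at the offset.
#' @return A list of class `allele_context`.
#' @export
allele_context <- function(variant_id, window, variant_offset, ref_allele,
                           alt_allele) {
  window <- toupper(window)
  if (!grepl("^[ACGT]+$", window)) stop("window must be over A/C/G/T")
  if (variant_offset < 0 ||
      variant_offset + nchar(ref_allele) > nchar(window))
    stop("variant_offset out of window")
  seen <- substr(window, variant_offset + 1L,
                 variant_offset + nchar(ref_allele))
  if (seen != toupper(ref_allele))
    stop("window does not carry the reference allele at the offset (saw '",
         seen, "', expected '", ref_allele, "')")
  structure(list(variant_id = variant_id, window = window,
                 variant_offset = as.integer(variant_offset),
                 ref_allele = toupper(ref_allele),
                 alt_allele = toupper(alt_allele)),
            class = "allele_context")
}

# substitute one allele for the other inside the window
apply_allele <- function(context, which = c("ref", "alt")) {
  which <- match.arg(which)
  if (which == "ref") return(context$window)
  paste0(substr(context$window, 1L, context$variant_offset),
         context$alt_allele,
         substr(context$window,
                context$variant_offset + nchar(context$ref_allele) + 1L,
                nchar(context$window)))
}

matches_motif <- function(tri, motifs) {
  suffix <- substr(tri, 2L, 3L)
  any(vapply(motifs, function(m) suffix == substr(m, 2L, 3L), logical(1)))
}

#' Enumerate PAM placements in a sequence
#'
#' Scans every trinucleotide window on both strands for membership in the
#' motif set (default NGG and NAG; the leading N is unconstrained).
#' Minus-strand placements are reported in plus-strand coordinates
#' (`position` is the 0-based start of the trinucleotide on the plus
#' strand) with the trinucleotide given as read 5'->3' on the minus strand.
#'
#' @param sequence DNA string.
#' @param motifs PAM motif set, default `c("NGG", "NAG")`.
#' @param strands Strands to scan, default both.
#' @return A data.frame with columns `position`, `strand`, `trinucleotide`.
#' @export
enumerate_pams <- function(sequence, motifs = c("NGG", "NAG"),
                           strands = c("+", "-")) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 3L)
    return(data.frame(position = integer(), strand = character(),
                      trinucleotide = character(), stringsAsFactors = FALSE))
  starts <- seq_len(n - 2L)
  tris <- substring(sequence, starts, starts + 2L)
  out <- list()
  suffixes <- substr(motifs, 2L, 3L)
  if ("+" %in% strands) {
    hit <- substr(tris, 2L, 3L) %in% suffixes
    out$plus <- data.frame(position = starts[hit] - 1L,
                           strand = rep("+", sum(hit)),
                           trinucleotide = tris[hit],
                           stringsAsFactors = FALSE)
  }
  if ("-" %in% strands) {
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(sequence, NULL)[[1]]), collapse = ""))
    rtris <- substring(rc, starts, starts + 2L)
    hit <- substr(rtris, 2L, 3L) %in% suffixes
    # minus-strand trinucleotide starting at rc position i covers plus
    # positions (n - i - 2) .. (n - i) (0-based)
    out$minus <- data.frame(position = n - (starts[hit] - 1L) - 3L,
                            strand = rep("-", sum(hit)),
                            trinucleotide = rtris[hit],
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# all (position, strand) placements whose trinucleotide overlaps the
# interval [lo, hi) (0-based) in a sequence of length n
overlapping_placements <- function(n, lo, hi) {
  pos <- seq.int(max(0L, lo - 2L), min(n - 3L, hi - 1L))
  if (length(pos) == 0L || pos[1L] > pos[length(pos)])
    return(data.frame(position = integer(), strand = character()))
  data.frame(position = rep(pos, each = 2L),
             strand = rep(c("+", "-"), length(pos)),
             stringsAsFactors = FALSE)
}

placement_is_pam <- function(sequence, position, strand, motifs) {
  n <- nchar(sequence)
  if (position < 0L || position + 3L > n) return(FALSE)
  tri <- substr(sequence, position + 1L, position + 3L)
  if (strand == "-") tri <- revcomp(tri)
  matches_motif(tri, motifs)
}

#' Test whether a variant creates a PAM in exactly one allele
#'
#' For SNVs, every placement (position, strand) whose trinucleotide overlaps
#' the variant base is tested for PAM membership on both allele sequences;
#' the variant is allele-specific when some placement is a PAM in exactly
#' one allele. An NGG in one allele and NAG in the other at the same
#' placement is *not* specific: both are functional PAMs. For indels, the
#' two allele sequences are compared for the presence of any PAM
#' overlapping the edited interval plus a 2-nt buffer on each side; the
#' variant is specific when exactly one allele carries at least one such
#' PAM.
#'
#' @param context An [allele_context()].
#' @param motifs PAM motif set, default `c("NGG", "NAG")`.
#' @return A list: `is_specific`, `sensitive_allele` (`"ref"`, `"alt"` or
#'   `NA`), and `placements`, a data.frame of allele-specific placements
#'   (`position`, `strand`, on the sensitive allele's coordinates) — empty
#'   when not specific. When both alleles gain PAMs at different placements
#'   the variant is reported not specific but flagged via the
#'   `both_alleles_gain` element.
#' @export
allele_specific_pam <- function(context, motifs = c("NGG", "NAG")) {
  stopifnot(inherits(context, "allele_context"))
  ref_seq <- apply_allele(context, "ref")
  alt_seq <- apply_allele(context, "alt")
  is_snv <- nchar(context$ref_allele) == 1L && nchar(context$alt_allele) == 1L
  off <- context$variant_offset
  if (is_snv) {
    pl <- overlapping_placements(nchar(ref_seq), off, off + 1L)
    ref_pam <- mapply(placement_is_pam, pl$position, pl$strand,
                      MoreArgs = list(sequence = ref_seq, motifs = motifs))
    alt_pam <- mapply(placement_is_pam, pl$position, pl$strand,
                      MoreArgs = list(sequence = alt_seq, motifs = motifs))
    ref_only <- as.logical(ref_pam) & !as.logical(alt_pam)
    alt_only <- as.logical(alt_pam) & !as.logical(ref_pam)
    both_gain <- any(ref_only) && any(alt_only)
    if (both_gain)
      return(list(is_specific = FALSE, sensitive_allele = NA_character_,
                  placements = pl[0, , drop = FALSE],
                  both_alleles_gain = TRUE))
    if (any(ref_only))
      return(list(is_specific = TRUE, sensitive_allele = "ref",
                  placements = pl[ref_only, , drop = FALSE],
                  both_alleles_gain = FALSE))
    if (any(alt_only))
      return(list(is_specific = TRUE, sensitive_allele = "alt",
                  placements = pl[alt_only, , drop = FALSE],
                  both_alleles_gain = FALSE))
    return(list(is_specific = FALSE, sensitive_allele = NA_character_,
                placements = pl[0, , drop = FALSE], both_alleles_gain = FALSE))
  }
  # indel: existence of any PAM overlapping the edited interval +/- 2 nt
  pam_in_buffer <- function(seq, allele_len) {
    lo <- off - 2L
    hi <- off + allele_len + 2L
    pams <- enumerate_pams(seq, motifs)
    keep <- pams$position + 3L > lo & pams$position < hi
    pams[keep, , drop = FALSE]
  }
  ref_hits <- pam_in_buffer(ref_seq, nchar(context$ref_allele))
  alt_hits <- pam_in_buffer(alt_seq, nchar(context$alt_allele))
  ref_has <- nrow(ref_hits) > 0L
  alt_has <- nrow(alt_hits) > 0L
  if (xor(ref_has, alt_has)) {
    sens <- if (ref_has) "ref" else "alt"
    hits <- if (ref_has) ref_hits else alt_hits
    list(is_specific = TRUE, sensitive_allele = sens,
         placements = hits[, c("position", "strand"), drop = FALSE],
         both_alleles_gain = FALSE)
  } else {
    list(is_specific = FALSE, sensitive_allele = NA_character_,
         placements = data.frame(position = integer(), strand = character()),
         both_alleles_gain = FALSE)
  }
}

#' Design the allele-specific guide for a specific placement
#'
#' The protospacer is the 20 nucleotides immediately 5' of the PAM on the
#' sensitive allele's targeted strand. For a minus-strand PAM the
#' protospacer is read off the minus strand (reverse complement of the plus
#' strand bases 3' of the placement).
#'
#' @param context An [allele_context()].
#' @param placement One row of the `placements` returned by
#'   [allele_specific_pam()] (`position`, `strand`).
#' @param sensitive_allele `"ref"` or `"alt"`.
#' @param motifs PAM motif set used to validate the placement.
#' @return A list of class `guide_design`: `protospacer` (20 nt), `strand`,
#'   `pam_sensitive`, `pam_resistant`, `sensitive_allele`.
#' @export
design_as_guide <- function(context, placement, sensitive_allele,
                            motifs = c("NGG", "NAG")) {
  stopifnot(inherits(context, "allele_context"),
            sensitive_allele %in% c("ref", "alt"))
  sens_seq <- apply_allele(context, sensitive_allele)
  res_seq <- apply_allele(context, setdiff(c("ref", "alt"), sensitive_allele))
  pos <- as.integer(placement$position)
  strand <- as.character(placement$strand)
  n <- nchar(sens_seq)
  read_tri <- function(seq, p) {
    if (p < 0L || p + 3L > nchar(seq)) return(NA_character_)
    tri <- substr(seq, p + 1L, p + 3L)
    if (strand == "-") revcomp(tri) else tri
  }
  is_snv <- nchar(context$ref_allele) == 1L && nchar(context$alt_allele) == 1L
  if (!placement_is_pam(sens_seq, pos, strand, motifs) ||
      (is_snv && placement_is_pam(res_seq, pos, strand, motifs)))
    stop("placement is not allele-specific: the sensitive allele must ",
         "carry a PAM the resistant allele lacks")
  if (strand == "+") {
    if (pos < 20L)
      stop("insufficient 5' flank for a 20-nt protospacer; widen the window")
    protospacer <- substr(sens_seq, pos - 20L + 1L, pos)
  } else {
    if (pos + 3L + 20L > n)
      stop("insufficient 5' flank for a 20-nt protospacer; widen the window")
    protospacer <- revcomp(substr(sens_seq, pos + 4L, pos + 23L))
  }
  structure(list(protospacer = protospacer, strand = strand,
                 pam_sensitive = read_tri(sens_seq, pos),
                 pam_resistant = read_tri(res_seq, pos),
                 sensitive_allele = sensitive_allele),
            class = "guide_design")
}

#' @export
print.guide_design <- function(x, ...) {
  cat("<guide_design>", x$protospacer, "PAM", x$pam_sensitive,
      "(", x$strand, "strand,", x$sensitive_allele, "allele sensitive vs",
      x$pam_resistant, ")\n")
  invisible(x)
}

#' Fraction of catalog variants with an allele-specific PAM
#'
#' @param contexts A list of [allele_context()] objects.
#' @param variants Optional variant data.frame (matched by `variant_id`)
#'   supplying consequence classes for the ORF restriction.
#' @param orf_classes_only Drop UTR-class variants before counting
#'   (requires `variants`).
#' @param motifs PAM motif set.
#' @return A list with `n_specific`, `n_total`, `fraction` (`NA` when
#'   `n_total` is 0).
#' @export
pam_fraction <- function(contexts, variants = NULL, orf_classes_only = FALSE,
                         motifs = c("NGG", "NAG")) {
  if (orf_classes_only) {
    if (is.null(variants))
      stop("orf_classes_only requires the variant table for classes")
    keep_ids <- variants$variant_id[
      variants$consequence_class %in% orf_consequence_classes()]
    contexts <- Filter(function(x) x$variant_id %in% keep_ids, contexts)
  }
  n_total <- length(contexts)
  if (n_total == 0L)
    return(list(n_specific = 0L, n_total = 0L, fraction = NA_real_))
  spec <- vapply(contexts, function(x)
    allele_specific_pam(x, motifs)$is_specific, logical(1))
  list(n_specific = sum(spec), n_total = n_total,
       fraction = sum(spec) / n_total)
}

#' Tabulate allele-specific guides for a set of contexts
#'
#' Runs [allele_specific_pam()] over every context and designs a guide for
#' each allele-specific placement with sufficient flank.
#'
#' @param contexts A list of [allele_context()] objects.
#' @param motifs PAM motif set.
#' @return A data.frame with columns `variant_id`, `sensitive_allele`,
#'   `strand`, `protospacer`, `pam_sensitive`, `pam_resistant` (zero rows
#'   when nothing is specific).
#' @export
design_guides <- function(contexts, motifs = c("NGG", "NAG")) {
  rows <- list()
  for (ctx in contexts) {
    asp <- allele_specific_pam(ctx, motifs)
    if (!asp$is_specific) next
    for (j in seq_len(nrow(asp$placements))) {
      g <- tryCatch(design_as_guide(ctx, asp$placements[j, ],
                                    asp$sensitive_allele),
                    error = function(e) NULL)
      if (is.null(g)) next
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = ctx$variant_id, sensitive_allele = g$sensitive_allele,
        strand = g$strand, protospacer = g$protospacer,
        pam_sensitive = g$pam_sensitive, pam_resistant = g$pam_resistant,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(variant_id = character(), sensitive_allele = character(),
                      strand = character(), protospacer = character(),
                      pam_sensitive = character(), pam_resistant = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
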