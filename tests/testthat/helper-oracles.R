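# Independent oracles, written against the definitions rather than the
# implementation under test.

# -- codon-table translation ------------------------------------------------
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), NULL)[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) - nchar(dna) %% 3
  if (n < 3) return("")
  codons <- substring(dna, seq(1, n, 3), seq(3, n, 3))
  paste(oracle_codon_table[codons], collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), NULL)[[1]]), collapse = "")
}

# -- exhaustive PAM enumeration ---------------------------------------------
# every (0-based plus-strand position, strand) whose trinucleotide, read
# 5'->3' on that strand, matches a motif (leading N free)
oracle_pam_set <- function(seq, motifs = c("NGG", "NAG")) {
  n <- nchar(seq)
  out <- character()
  if (n < 3) return(out)
  sfx <- substr(motifs, 2, 3)
  for (p in 0:(n - 3)) {
    tri <- substr(seq, p + 1, p + 3)
    if (substr(tri, 2, 3) %in% sfx) out <- c(out, paste0(p, ":+"))
    rc <- oracle_revcomp(tri)
    if (substr(rc, 2, 3) %in% sfx) out <- c(out, paste0(p, ":-"))
  }
  out
}

# exhaustive allele-specificity: compare the complete PAM placement sets of
# the two allele sequences; specific iff placements exist on exactly one
# side of the difference
oracle_allele_specific <- function(window, offset, ref, alt,
                                   motifs = c("NGG", "NAG")) {
  alt_seq <- paste0(substr(window, 1, offset), alt,
                    substr(window, offset + nchar(ref) + 1, nchar(window)))
  ref_set <- oracle_pam_set(window, motifs)
  alt_set <- oracle_pam_set(alt_seq, motifs)
  ref_only <- setdiff(ref_set, alt_set)
  alt_only <- setdiff(alt_set, ref_set)
  if (length(ref_only) > 0 && length(alt_only) > 0)
    return(list(is_specific = FALSE, sensitive_allele = NA_character_))
  if (length(ref_only) > 0)
    return(list(is_specific = TRUE, sensitive_allele = "ref"))
  if (length(alt_only) > 0)
    return(list(is_specific = TRUE, sensitive_allele = "alt"))
  list(is_specific = FALSE, sensitive_allele = NA_character_)
}

# -- Benjamini-Hochberg step-up, brute force --------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(vapply(rank_i:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q
}

# -- Welch t closed form ----------------------------------------------------
oracle_welch_p_less <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  pt(t, df)
}

random_window <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small config used across tests to keep runtimes low
tiny_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_genes = 30L, n_essential = 6L,
               n_samples_per_type = c(ACC = 20L, LUAD = 20L),
               loh_rate_per_type = c(ACC = 0.45, LUAD = 0.21),
               n_cell_lines = 8L)
  override <- list(...)
  do.call(simulation_config, c(override, args[setdiff(names(args),
                                                      names(override))]))
}
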