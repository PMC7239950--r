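# builds a 61-nt window whose central base is the SNV, with fixed flanks
# free of surprises only via the oracle (flanks are random; the oracle
# decides the expected outcome)
central_snv_context <- function(window, ref = NULL, alt = "G", id = "v") {
  off <- (nchar(window) - 1L) %/% 2L
  ref <- substr(window, off + 1L, off + 1L)
  allele_context(id, window, off, ref, alt)
}

test_that("PAM enumeration finds every NGG/NAG placement on both strands", {
  hits <- enumerate_pams("AAGGA")
  expect_true(any(hits$position == 1 & hits$strand == "+" &
                    hits$trinucleotide == "AGG"))
  expect_equal(nrow(enumerate_pams("TTTTT")), 0L)
  minus <- enumerate_pams("CCA")
  expect_equal(minus$strand, "-")
  expect_equal(minus$trinucleotide, "TGG")
  expect_equal(minus$position, 0)
  # exhaustiveness against the oracle on random sequences
  set.seed(5)
  for (i in 1:50) {
    w <- random_window(15)
    got <- enumerate_pams(w)
    keys <- if (nrow(got) > 0L) paste0(got$position, ":", got$strand)
            else character(0)
    expect_equal(sort(keys), sort(oracle_pam_set(w)))
  }
})

test_that("SNV allele specificity matches the worked placements", {
  # ref C gives ACG (no PAM); alt G gives AGG: specific, alt-sensitive
  w <- paste0(strrep("T", 29), "A", "C", "G", strrep("T", 29))
  ctx <- allele_context("v", w, 30L, "C", "G")
  asp <- allele_specific_pam(ctx)
  expect_true(asp$is_specific)
  expect_equal(asp$sensitive_allele, "alt")

  # SNV at the N position: TGG vs CGG are both PAMs -> not specific
  w <- paste0(strrep("T", 30), "T", "GG", strrep("T", 28))
  ctx <- allele_context("v", w, 30L, "T", "C")
  expect_false(allele_specific_pam(ctx)$is_specific)

  # NGG <-> NAG at the same placement: both in the motif set -> not specific
  w <- paste0(strrep("T", 30), "G", "G", strrep("T", 29))
  ctx <- allele_context("v", w, 30L, "G", "A")   # TGG -> TAG
  expect_false(allele_specific_pam(ctx)$is_specific)
  # but with NGG alone it is specific (NAG no longer counts as a PAM)
  ngg_only <- allele_specific_pam(ctx, motifs = "NGG")
  expect_true(ngg_only$is_specific)
  expect_equal(ngg_only$sensitive_allele, "ref")
})

test_that("SNV specificity agrees with exhaustive enumeration (random)", {
  set.seed(9)
  for (i in 1:300) {
    w <- random_window(11)
    off <- 5L
    ref <- substr(w, off + 1L, off + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    got <- allele_specific_pam(allele_context("v", w, off, ref, alt))
    want <- oracle_allele_specific(w, off, ref, alt)
    expect_equal(got$is_specific, want$is_specific, info = w)
    if (want$is_specific)
      expect_equal(got$sensitive_allele, want$sensitive_allele, info = w)
  }
})

test_that("specificity is invariant under reverse complement of the window", {
  set.seed(13)
  for (i in 1:100) {
    w <- random_window(9)
    off <- 4L
    ref <- substr(w, off + 1L, off + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    fwd <- allele_specific_pam(allele_context("v", w, off, ref, alt))
    rc <- oracle_revcomp(w)
    rc_ref <- oracle_revcomp(ref); rc_alt <- oracle_revcomp(alt)
    rev <- allele_specific_pam(allele_context("v", rc, 4L, rc_ref, rc_alt))
    expect_equal(fwd$is_specific, rev$is_specific, info = w)
  }
})

test_that("indels are compared by PAM existence around the edited interval", {
  # insertion creating a GG completes a PAM absent from the ref allele
  w <- paste0(strrep("T", 30), "A", strrep("T", 30))
  ctx <- allele_context("v", w, 30L, "A", "AGG")
  asp <- allele_specific_pam(ctx)
  expect_true(asp$is_specific)
  expect_equal(asp$sensitive_allele, "alt")
  # both alleles PAM-free -> not specific
  ctx2 <- allele_context("v", w, 30L, "A", "ATT")
  expect_false(allele_specific_pam(ctx2)$is_specific)
})

test_that("guide design takes the 20 nt 5' of the PAM on the right strand", {
  proto <- strrep("ACGT", 5)
  w <- paste0(strrep("T", 9), proto, "A", "C", "G", strrep("T", 29))
  ctx <- allele_context("v", w, 30L, "C", "G")
  asp <- allele_specific_pam(ctx)
  expect_true(asp$is_specific)
  pl <- asp$placements[asp$placements$position == 29 &
                         asp$placements$strand == "+", ]
  g <- design_as_guide(ctx, pl, asp$sensitive_allele)
  expect_equal(g$protospacer, proto)
  expect_equal(g$pam_sensitive, "AGG")
  expect_equal(g$pam_resistant, "ACG")
  # resistant allele differs from sensitive only inside the PAM
  expect_equal(nchar(g$protospacer), 20L)

  # non-specific placement is rejected
  expect_error(design_as_guide(ctx, data.frame(position = 0, strand = "+"),
                               "alt"),
               "not allele-specific")
  # insufficient flank: specific placement too close to the window edge
  short <- allele_context("v", paste0("TTACG", strrep("T", 10)), 3L, "C", "G")
  sp <- allele_specific_pam(short)
  expect_true(sp$is_specific)
  pl1 <- sp$placements[sp$placements$strand == "+", ][1, ]
  expect_error(design_as_guide(short, pl1, sp$sensitive_allele), "flank")
})

test_that("emitted guides re-scan to exactly their site on the sensitive allele", {
  set.seed(21)
  n_checked <- 0L
  while (n_checked < 25L) {
    w <- random_window(61)
    off <- 30L
    ref <- substr(w, off + 1L, off + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    ctx <- allele_context("v", w, off, ref, alt)
    asp <- allele_specific_pam(ctx)
    if (!asp$is_specific) next
    sens_seq <- if (asp$sensitive_allele == "ref") w else
      paste0(substr(w, 1, off), alt, substr(w, off + 2, nchar(w)))
    for (j in seq_len(nrow(asp$placements))) {
      g <- tryCatch(design_as_guide(ctx, asp$placements[j, ],
                                    asp$sensitive_allele),
                    error = function(e) NULL)
      if (is.null(g)) next
      target <- paste0(g$protospacer, g$pam_sensitive)
      strand_seq <- if (g$strand == "+") sens_seq else oracle_revcomp(sens_seq)
      expect_true(grepl(target, strand_seq, fixed = TRUE), info = w)
      n_checked <- n_checked + 1L
    }
  }
})

test_that("pam_fraction counts the ORF subset and handles empty input", {
  w_spec <- paste0(strrep("T", 29), "A", "C", "G", strrep("T", 29))
  w_null <- strrep("T", 61)
  ctxs <- list(allele_context("v1", w_spec, 30L, "C", "G"),
               allele_context("v2", w_null, 30L, "T", "A"),
               allele_context("v3", w_null, 30L, "T", "A"),
               allele_context("v4", w_null, 30L, "T", "A"))
  res <- pam_fraction(ctxs)
  expect_equal(res$fraction, 0.25)

  variants <- data.frame(variant_id = paste0("v", 1:4),
                         consequence_class = c("missense_variant",
                                               rep("3_prime_UTR_variant", 3)),
                         stringsAsFactors = FALSE)
  orf <- pam_fraction(ctxs, variants, orf_classes_only = TRUE)
  expect_equal(orf$n_total, 1L)
  expect_equal(orf$fraction, 1)
  utr_only <- pam_fraction(ctxs[2:4], variants, orf_classes_only = TRUE)
  expect_equal(utr_only$n_total, 0L)
  expect_true(is.na(utr_only$fraction))
})
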