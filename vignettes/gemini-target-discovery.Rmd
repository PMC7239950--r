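---
title: "Discovering allele-specific vulnerabilities from LOH in essential genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering allele-specific vulnerabilities from LOH in essential genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geminir)
```

## The model

A tumor that loses one allele of a heterozygous locus (loss of
heterozygosity, LOH) inside a pan-essential gene becomes dependent on the
remaining allele, while normal tissue keeps both. Any agent that inactivates
specifically the retained allele — an allele-selective CRISPR guide, siRNA,
or small molecule — should kill the tumor cell and spare the host. `geminir`
finds the (common germline variant, essential gene) pairs where this
situation arises and scores each one.

Three measurable quantities drive the analysis:

* **Heterozygosity** χ of a biallelic locus with minor allele frequency
  *p*, estimated under Hardy–Weinberg as χ = 2*p*(1 − *p*). We deliberately
  use the expectation rather than observed genotype counts: the population
  inputs the package emulates report allele frequencies, not genotypes.
  χ ≤ 0.5 always, with the maximum at *p* = 0.5.
* **LOH rate** λ of a gene: the fraction of tumors with a call at the gene
  whose minor allelic copy number is zero. Calls come from
  purity/ploidy-corrected integer allelic segments; the gene-level call is
  taken from the overlapping segment with the largest overlap.
* **Patient reach** Π = κ · χ · λ · 0.5, where κ is annual cancer incidence
  (default 1,735,350 US cases/year) and the factor 0.5 assumes the lost
  allele is random, so half of LOH events remove the allele a therapeutic
  would target.

```{r}
chi <- heterozygosity(0.177)
chi
patients_per_year(chi = chi, lam = 0.09)
```

## Thresholds and their meaning

| Parameter | Default | Meaning |
|---|---|---|
| `maf_min` | 0.01 | minimum minor allele frequency for a "common" variant (inclusive) |
| `fdr` | 0.10 | per-screen FDR below which a gene counts as essential in that screen (strict `<`) |
| `ceres_cut` | −0.4 | genes with mean CERES above this are insufficiently dependent (strict `>` excludes; the boundary is retained) |
| `demeter2_cut` | −0.5 | median DEMETER2 at or below this marks a strong RNAi dependency (inclusive) |
| `log2_loss_cut` | −0.1 | LOH with gene-level log2 relative copy number at or below this is copy-loss; above, copy-neutral |
| `kappa` | 1,735,350 | annual incidence used for patient-reach estimates |
| `motifs` | NGG, NAG | *S. pyogenes* PAM set; NAG is the weaker non-canonical motif |

All of these are `pipeline_config()` fields, never hard-coded in the stage
logic, so sensitivity analyses are one-argument changes. Boundary behaviour
at each threshold is pinned by dedicated tests.

## The essential-gene cascade

Evidence from three haploid loss-of-function screens nominates candidates:
two CRISPR screens contribute ready-made q-values, and gene-trap insertion
counts are scored in-package. Under the null, a gene-trap insertion lands in
sense or antisense orientation with equal probability; essential genes
deplete disruptive sense insertions, so the p-value is the exact lower
binomial tail P(X ≤ sense | n, 0.5), Benjamini–Hochberg adjusted across
tested genes. The tail is one-sided by design — only sense depletion is
evidence of essentiality; a sense excess is not.

Candidates then pass through exclusion filters in a fixed order: CCLE
loss-of-function evidence (homozygous deletion at log2 CN < −5 in more than
two cell lines; expression under 0.5 RPKM in more than five lines; or a
single line with homozygous deletion *and* expression under 1.0 RPKM — the
last criterion requires both conditions in the same line), then mean CERES.
Genes with no CCLE data cannot be cleared by the CCLE filter and are instead
rescued when they scored in at least two screens with mean CERES strictly
below −0.4; a rescued gene trivially satisfies the CERES filter. Tier 1
tumor suppressors are removed last (inactivating a tumor suppressor's
remaining allele is not a therapeutic strategy), and genes absent from the
tumor copy-number data are dropped because λ is undefined for them.

## Allele-specific PAM logic

A Cas9 guide needs a PAM immediately 3′ of its 20-nt protospacer. A germline
SNV can create a PAM in one allele and not the other, making the PAM-bearing
("sensitive") allele cleavable and the other ("resistant") allele immune.
For an SNV, every trinucleotide placement overlapping the variant base is
tested on both strands of both allele sequences; the variant is specific
when some placement is a PAM in exactly one allele. Two deliberate
subtleties:

* An NGG↔NAG change at the same placement is **not** specific — both motifs
  support cleavage, so discrimination is lost.
* When *both* alleles gain PAMs at *different* placements, the variant is
  reported not-specific (each allele could be cut by some guide) but the
  condition is flagged, since each placement alone could still
  discriminate.

Indel alleles shift coordinates, so they are compared by existence: the two
allele sequences are scanned for any PAM overlapping the edited interval
plus a 2-nt buffer, and the variant is specific when exactly one allele has
at least one. The default 61-nt variant-anchored window guarantees room for
a 20-nt protospacer plus PAM on either strand. The implementation is tested
for exact agreement with brute-force trinucleotide enumeration over all 4^7
central-SNV windows and for invariance under reverse complement.

UTR variants are excluded from PAM analysis (12 of the 14 admitted
consequence classes remain): disrupting an untranslated region does not
reliably knock out the protein.

## The per-gene LOH transformation

The segment-to-gene rule is the one genuinely open design choice: the
transformation from segments to gene calls could use maximal overlap,
midpoints, or full containment. We use **maximal overlap with ties to the
leftmost segment start** — deterministic, least surprising, and exercised by
an explicit 50/50-tie test. Genes without an overlapping segment in a sample
are *missing*, not non-LOH, and leave rate denominators; counting them as
non-LOH would deflate rates on sparse cohorts. Sex-chromosome genes are
carried through with `loh_class = "none"` (hemizygosity is not LOH) so gene
counts reconcile across outputs.

## What the synthetic cohort emulates

The generator produces every input the pipeline reads, with planted ground
truth:

* **Variants**: ~3 per gene (Poisson), MAF uniform on [0.01, 0.5], a
  coding-heavy consequence mix, plus configurable decoys (MAF < 0.01 and
  non-PASS) that must be filtered out. A configurable fraction of coding
  SNVs (default 23%) is constructed so that exactly one allele completes a
  PAM in its 61-nt context, verified at generation time; all other contexts
  are verified non-specific.
* **Segments**: per sample and gene, minor copy drops to zero with the tumor
  type's planted LOH rate (defaults 0.45/0.21/0.09/0.01 across four types,
  spanning the observed range), of which 28% are copy-neutral (major 2,
  log2 > −0.1) and the rest copy-loss (major 1, log2 ≤ −0.1). Each gene
  segment gets a neutral flanking segment so overlap assignment is
  exercised.
* **Screens**: planted essential genes (default 100 of 1000) draw low
  q-values, sense-depleted gene traps (p_sense = 0.15 vs 0.5), and
  CERES/DEMETER2 centered at −2 × `essential_effect` (default −1.0); nulls
  draw balanced and near-zero values. Small planted subsets trigger each
  CCLE exclusion rule and the missing-data rescue path. Setting
  `essential_effect = 0` removes all planting.
* **Annotations**: the five structural/enzyme criteria are independent
  draws; the charge and cysteine flags are computed from the simulated
  amino-acid change itself, so they are consistent by construction.

What the generator does **not** model: linkage and recombination, subclonal
copy number, purity/ploidy error (its segments are already integer truth),
gene-length variation, mutational signatures, and correlated screen noise.
Passing tests therefore demonstrate that the *pipeline logic* is correct
under the stated generative assumptions — not that it is robust to
real-data artifacts such as noisy ABSOLUTE fits or batch effects.

## Numerical and interface choices

* All internal coordinates are 0-based half-open; VCF and segment tables
  (1-based inclusive) convert at the I/O boundary, BED passes through.
* Alternate-allele frequencies above 0.5 fold to MAF at read time, so all
  downstream math sees minor allele frequency; `heterozygosity()` rejects
  unfolded input rather than silently refolding.
* Multi-allelic sites are treated as independent ref/alt pairs.
* Median of an even-length vector is the midpoint mean (`stats::median`).
* The enrichment test is an exact binomial tail against the background
  proportion; the Yates χ² clamps |O − E| − 0.5 at zero (matching
  `chisq.test(correct = TRUE)`, which doubles as a cross-check in tests).
* Histidine is counted as positively charged (conventional
  physiological-pH classes: D/E negative, K/R/H positive).
* Missing matrix cells stay `NA` everywhere — means and medians use
  non-missing entries only, and a CERES mean of exactly −0.4 is retained.
* Every generator seeds its own stream from `seed` plus a fixed offset, so
  stages are individually reproducible and order-independent; a fixed seed
  makes the whole pipeline byte-identical across runs.

## Problem sizes

The shipped tests validate parameter recovery at 500 samples per tumor type
across four types and 40 genes (planted LOH rates recovered within three
binomial standard errors, copy-neutral share 0.28 likewise), cascade
sensitivity and specificity ≥ 0.95 at 1000 genes with 100 planted essential,
and exhaustive PAM-oracle agreement on all 16,384 length-7 windows; these
sizes give tight Monte-Carlo error while keeping the default suite under a
minute of simulation time.

## Known limitations

* Heterozygosity is the Hardy–Weinberg expectation; cohorts with observed
  genotype counts could substitute empirical heterozygosity, which this
  package does not compute.
* Guide design reports no off-target or efficacy scores, and only
  *S. pyogenes* NGG/NAG PAMs are supported.
* Druggability inputs are consumed as annotation tables; the package does
  not re-derive structure-based druggability or run homology searches.
* The indel PAM rule (existence within a ±2-nt buffer) is one reasonable
  convention; coordinate-shifted placements admit no unique per-placement
  comparison.
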