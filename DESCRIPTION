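Package: geminir
Title: Discovery and Prioritization of Allele-Specific Vulnerabilities from
    Loss of Heterozygosity in Essential Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies common germline variants in pan-essential genes whose
    heterozygosity is lost in tumors (GEMINI vulnerabilities) and scores their
    targetability. Implements per-gene loss-of-heterozygosity (LOH) calling
    from allelic copy-number segment tables, an essential-gene filter cascade
    over haploid loss-of-function screens with gene-trap binomial FDR, CCLE
    copy-number/expression exclusion rules and a CERES dependency filter,
    allele-specific Cas9 PAM discovery (NGG/NAG) with 20-nt protospacer
    design, Hardy-Weinberg heterozygosity, theoretical patient-reach
    estimates, RNAi dependency classification, and a 0-7 druggability
    composite. A synthetic-cohort generator emulates the population variant,
    tumor copy-number, and dependency-screen inputs so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
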