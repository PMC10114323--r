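Package: triosv
Title: Trio-Based Discovery and Characterisation of De Novo Structural Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens population structural-variant (SV) callsets from
    sire-dam-proband trios for de novo structural variants (dnSVs).
    Implements a Mendelian candidate screen, genotype-quality, allele
    frequency and depth fold-change (DHFFC/DHBFC) filter cascades for
    deletions, duplications and inversions, a rule-based proxy for manual
    breakpoint inspection, parent-of-origin assignment from informative
    SNPs, breakpoint micro-homology mechanism classification, mutation
    clustering, mosaic cell-fraction inference, transmission checks in
    sequenced third-generation offspring, and per-generation dnSV rate
    estimation with a Wilson confidence interval. A pedigree-structured
    synthetic cohort generator with planted ground truth makes every
    stage testable without access to animal sequence data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
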