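Package: sibhap
Title: Haplotype Fine-Mapping and Functional Follow-Up for Discordant Sibling
    Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extreme-phenotype sibling-pair association studies of
    candidate modifier loci and their trans-acting partners. Implements
    centile-based severity classification and concordant/discordant pair
    calling, EM estimation of multilocus haplotype frequencies from unphased
    genotypes with weighted phase-explanation lists, likelihood-ratio
    haplotype association with pair-preserving permutation and min-p
    multiple-testing correction, transmission disequilibrium tests, D-prime
    linkage-disequilibrium blocks and signal localization, divergent-site
    calling on resequenced haplotypes, allele-specific position-weight-matrix
    scanning, a contaminant-filtering cascade for gel-shift protein
    mass-spectrometry (EMSA-PSeq) identifications, intron-retention
    (read-through) transcript and truncated-ORF modelling, nested delta-delta-Ct
    qPCR quantification with rank tests, and a seed-deterministic synthetic
    cohort generator embodying a cis-by-trans phenotype model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    digest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
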