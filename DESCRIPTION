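Package: polycis
Title: Polygenic Cis-Regulatory Selection from Allele-Specific Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects lineage-specific selection on cis-regulation from the
    directionality of allele-specific expression (ASE) in interspecies
    hybrids, and dissects its phenotypic consequences. Provides ASE
    quantification from allele-resolved read counts (coverage filtering,
    exact binomial allele-bias and treatment-response tests, BH false
    discovery control), the directional sign test for polygenic selection
    (hypergeometric stratum enrichment plus a binomial directionality test,
    with gene-set scans and permutation calibration), joint ASE/induction
    candidate-gene selection, plate-reader growth-curve kinetics (sliding
    window maximum growth rate, toxin-effect log-ratios), pooled
    barcode-competition fitness estimation (exact barcode matching,
    per-generation selection coefficients, dilution-scheme generation
    accounting), Fitch parsimony reconstruction of binary trait histories,
    and seeded synthetic-data generators with ground truth so every stage
    is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
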