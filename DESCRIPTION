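Package: TGCTools
Title: Clonal Timing, Methylation Deconvolution, and Cohort Statistics
    for Testicular Germ Cell Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Inference layer for integrated molecular analysis of testicular
    germ cell tumors (TGCTs). Computes mutation multiplicity from tumor
    variant allele fraction, copy number and purity, and times somatic
    mutations relative to whole-genome doubling and isochromosome 12p
    formation; calls WGD count, i(12p), 12q LOH and arm-level events from
    allelic integer copy number; estimates infiltrating-lymphocyte fraction
    from methylation signature probes and corrects beta values for the
    two-component tumor/lymphocyte mixture; scores non-CpG (CpH) methylation,
    surveys imprinted DMRs, and calls promoter epigenetic silencing against
    expression; and provides the cohort-level statistics (mutation spectrum
    fractions, odds ratios, chi-square, rank-sum tests, immune signature
    scores) behind the KIT-mutant seminoma subtype. A synthetic cohort
    generator with recorded ground truth makes every stage testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, CopyNumberVariation, SomaticMutation, Epigenetics
RoxygenNote: 7.3.3
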