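Package: gbsland
Title: SNP Landscape, Annotation and Diversity Analysis for Genotyping-by-Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling analysis of genotyping-by-sequencing (GBS)
    SNP call sets in diploids: depth/presence/minor-allele-frequency quality
    filtering, SNP-landscape summaries (transition/transversion spectrum,
    per-accession heterozygosity, chromosome coverage and gap statistics,
    windowed density tracks, SNP-array cross-referencing), genomic-context
    classification and SnpEff-style variant-effect prediction against GFF3
    gene models, and genetic-diversity analysis (identity-by-state distances,
    UPGMA dendrograms, principal components, and a maximum-likelihood
    admixture model with Evanno delta-K model selection). Includes a
    synthetic-data generator that emits a toy reference genome, gene models,
    planted variants with known truth labels, and genotypes drawn from a
    Balding-Nichols population model, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    generics,
    vcfR,
    ape,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
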