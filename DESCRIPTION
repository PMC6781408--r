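Package: tailscan
Title: Single-Plant Association and Bulk Segregant Scans in
    Truncation-Selected Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for mapping quantitative trait loci in heterogeneous,
    random-mating crop populations using unreplicated single-plant
    phenotypes. Couples a genome-wide association scan on individual
    plants (with generation and selection-regime covariates and an
    iterative pseudo-QTN refinement) with a modified bulk segregant
    analysis that contrasts allele frequencies between in-silico bulks
    descended from divergent ~5% truncation selection, using a pooled
    two-proportion Z test, an empirical outlier threshold, 15-SNP
    sliding-window smoothing and region calling. Includes marker
    filtering, naive mean imputation, genomic relationship matrices,
    PCA, realized and GREML heritability, candidate-gene annotation
    from GFF3, and a forward simulator of the full divergent-selection
    experiment (linked markers, additive QTL, truncation selection,
    random mating with recombination, and low-depth
    genotyping-by-sequencing observation) providing ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
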