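Package: refchip
Title: Reference-Peak Normalization for Quantitative Differential ChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Normalization of differential ChIP-seq experiments with genome-wide
    occupancy changes, using an internal standard of unchanged reference peaks
    (parallel-factor or spike-in controls). Derives per-sample size factors and a
    between-condition normalization coefficient from control-peak read counts by
    through-origin linear regression, corrects MA-plot fold-changes, and feeds the
    corrected scaling into a negative-binomial Wald test of differential binding
    with Benjamini-Hochberg FDR control. Includes peak-set algebra (species
    partitioning of combined-genome peaks, control-peak exclusion filters,
    consensus peaks), read counting in peaks from indexed BAM files, subsampling
    stability analysis of the normalization coefficient, cross-normalization of
    single-factor to parallel-factor experiments, and a synthetic-data generator
    reproducing the statistical structure the method assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
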