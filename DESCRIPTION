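Package: enhancerscape
Title: Enhancer Classification and SWI/SNF Binding Dynamics from ChIP-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A post-alignment toolkit for classifying cell type-specific
    enhancers from ChIP-Seq, ATAC-Seq and RNA-Seq read tracks. Implements a
    window/gap Poisson island caller with Benjamini-Hochberg FDR control
    (broad-mark and narrow-factor regimes), chromatin-state classification of
    regions into promoters, active and primed enhancers (H3K4me1/H3K27ac),
    SWI/SNF sub-complex (BAF/PBAF/GBAF) assignment by subunit co-occupancy,
    temporal and perturbation-dependency labelling of enhancers (prebound vs
    de novo binding, pioneer-factor activation, ATPase-depletion dependency),
    spike-in aware signal quantification (binned heatmap matrices, average
    profiles, center-window ranking), one-sided Wilcoxon signed-rank
    fold-change tests, and RPKM-based differential expression. A synthetic
    landscape generator with programmed ground truth makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
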