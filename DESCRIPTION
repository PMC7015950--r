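Package: wheatrhizo
Title: Wheat Rhizosphere and Root Microbiota Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Re-implementation of a wheat rhizosphere/root amplicon microbiota
    analysis as a tested, reusable pipeline. Provides validated readers for
    OTU count, taxonomy, sample-metadata and qPCR Ct tables; a
    Dirichlet-multinomial synthetic community generator that emulates a
    multi-species wheat glasshouse design with known ground truth; host and
    organelle OTU removal, depth standardization by subsampling, relative
    abundance and square-root transformation; a 16S/18S qPCR
    eukaryote-to-prokaryote contribution estimator with host-plant DNA
    correction; prevalence-based core microbiota and Venn partitioning;
    Bray-Curtis distances, principal coordinates analysis, multifactorial and
    nested PERMANOVA with sequential or marginal sums of squares under
    reduced-model residual permutation, and canonical analysis of principal
    coordinates; and taxon-level ANOVA/pairwise screens with compact letter
    displays, Pearson taxon-taxon correlation and fold-change flagging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
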