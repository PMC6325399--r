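Package: rumenTRFLP
Title: T-RFLP Community Fingerprinting, qPCR Relative Quantification and
    Split-Plot Statistics for Rumen Microbiome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline from raw terminal restriction fragment
    length polymorphism (T-RFLP) peak tables and quantitative real-time
    PCR Ct values to microbial community diversity, community-structure
    ordination, relative bacterial abundances and species-by-diet
    statistics for rumen fermentation variables. Implements iterative
    true-peak detection against a zero-mean background, cross-sample
    fragment-length binning, within-sample standardization, Shannon and
    inverse-Simpson diversity, Euclidean-distance complete-linkage
    clustering and principal component analysis, 2^-deltaCt relative
    quantification with fold-change summaries, and the classic balanced
    split-plot analysis of variance with Tukey pairwise comparisons.
    Includes a synthetic-data generator that emulates electropherograms,
    Ct tables and fermentation records with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
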