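Package: gsisEvol
Title: Evolutionary Analysis of the Glucose-Stimulated Insulin Secretion
    Protein Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-conservation, gene-age and gene-duplication analysis of
    the 69-protein core network underlying glucose-stimulated insulin
    secretion (GSIS) in pancreatic beta-cells. Provides the transcribed study
    tables as a packaged fixture; Needleman-Wunsch global alignment summaries
    (percent identity/similarity under BLOSUM62); phylogenetic-age
    classification (Universal/Eukaryote/Metazoan/Vertebrate) from homology-hit
    profiles with shared-homologue cluster detection; duplication-history
    vectors extracted from NHX gene trees, their hierarchical clustering and
    Mann-Whitney group (anti)clustering tests; the pathway-divergence ANOVA
    with Tukey HSD, composition chi-squared, Spearman correlation and
    disease-gene comparisons; synthetic-data generators with known ground
    truth; and an end-to-end pipeline producing JSON/TSV reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
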