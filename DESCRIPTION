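Package: micrometab
Title: Metabolic Activity Scores for 16S Microbiome Data via Genome-Scale Reconstructions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts 16S rRNA taxonomic abundance tables into normalized
    reaction- and subsystem-level metabolic activity scores by mapping
    taxa onto curated collections of strain-level genome-scale metabolic
    reconstructions (AGORA/AGREDA-style bundles). Relative taxon
    abundances (matrix X) are combined with strain-presence ratios of
    reactions (matrix R) to give reaction activity scores W = R X, which
    are aggregated into subsystem scores Y = S W through a subsystem
    normalization matrix S. Includes nonparametric differential activity
    analysis (Wilcoxon rank-sum with Benjamini-Hochberg correction and a
    mean-difference effect size), exploratory analysis (PCA, silhouette
    scoring of group separation, hierarchically clustered heatmap
    ordering), synthetic fixture generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    cluster,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
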