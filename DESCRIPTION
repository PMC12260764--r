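Package: mangroveBiomass
Title: Plotless Stand Sampling and Allometric Organ Weights for Mangrove Forests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates spatially explicit Avicennia germinans stands for three
    mangrove ecosystem conditions (natural, degraded, restored), performs
    point-centered quarter method (PCQM) transect sampling with a truncated
    search radius, estimates stand structure (density, basal area, diameter
    classes), computes per-tree trunk, aboveground and root dry weights from
    published power-law allometric equations, scales organ weights to a
    per-hectare basis, and runs the accompanying inferential pipeline
    (log10 normality screening, Kruskal-Wallis with Dunn post-hoc pairwise
    comparisons, Spearman organ-organ rank correlations, and a Gaussian GLM of
    total tree weight on ecosystem type).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
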