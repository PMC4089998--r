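Package: odorcolor
Title: Cross-Cultural Color-Odor Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing crossmodal color-odor association data from
    forced-choice experiments in which participants pick the three most
    congruent and three most incongruent colors for each odor from a 36-color
    palette. Compiles per-odor 72-feature color patterns, tests within-group
    choice consistency with chi-square statistics, classifies odors from
    color patterns with a shrinkage Fisher linear discriminant under
    shuffled-fold cross-validation and a color-permutation null, and
    quantifies within- and between-group representational (dis)similarity
    via first- and second-order representational dissimilarity matrices.
    Includes a seeded Dirichlet-profile generator of synthetic response
    datasets with tunable within-group consistency and cross-group sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
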