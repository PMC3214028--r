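Package: barcodeSurvey
Title: Species Richness Estimation from Plant DNA Barcode Plot Surveys
Version: 0.1.0
Authors@R:
    person("Plot", "Surveyor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the species richness of a vegetation plot from
    multi-locus DNA barcode data (e.g. chloroplast rbcLa, matK, trnH-psbA).
    Implements maximum-composite-likelihood pairwise distances (pooled TN93),
    deterministic neighbor-joining trees with nonparametric bootstrap,
    delimitation of hypothetical species as maximal monophyletic groups with
    zero pairwise distance, species discrimination and richness estimation
    accuracy statistics, multilocus concatenation with simple indel coding and
    short-inversion normalization, Faith's phylogenetic diversity, and a
    fully ground-truthed plot-survey simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
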