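Package: spicoda
Title: Compositional Data Analysis of Biomineral Elemental Compositions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing elemental compositions of
    calcareous skeletal elements (spicules) measured by energy-dispersive X-ray
    spectrometry. Implements the log-ratio toolbox of compositional data
    analysis (closure, amalgamation, CLR/ILR transforms, compositional centers,
    variation matrices, total variance, weighted Aitchison distances),
    agglomerative Ward clustering in log-ratio geometry with silhouette-based
    cluster-number selection, multivariate group comparison in ILR coordinates
    (Wilks' lambda MANOVA and pairwise Hotelling tests, parametric or
    permutation), descriptive cluster summaries (ratio tables, ternary and
    biplot coordinates, log-ratio boxplot statistics), a seeded synthetic-data
    generator for logistic-normal cluster scenarios, and Raman spectrum
    processing for calcite-family mineral identification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    cluster,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
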