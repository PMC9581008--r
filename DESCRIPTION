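Package: immunosig
Title: Differential Reactivity Analysis of Peptide Immunoarrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for peptide microarray immunoprofiling
    (immunosignature) experiments. Reads GenePix results (GPR/ATF) or
    four-column spot CSV files, computes foreground, background-subtracted,
    or background-scaled spot intensities, aggregates replicate spots,
    normalizes across arrays (none, quantile, or arsinh variance
    stabilization), screens peptides for differential reactivity between two
    cohorts with Mann-Whitney U tests and Benjamini-Hochberg false discovery
    rate control, clusters samples (UPGMA, k-means, PCA, cluster quality
    indices), and builds synoptic and targeted visualizations: boxplots,
    mean-variance and mean-median plots, heatmaps, swarm/strip plots,
    positional line graphs, and epitope maps. Includes a synthetic-data
    generator emulating tiled overlapping peptides printed in replicate with
    cohort effects and spatially varying background.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    grDevices,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
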