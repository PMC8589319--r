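Package: diglyq
Title: Quantitative diGLY Ubiquitylome Profiling from TMT-MS3 Reporter Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for lysine-GlyGly (diGLY)
    remnant ubiquitylome experiments quantified by isobaric tandem mass
    tags with MS3 reporter-ion readout. Takes searched peptide-spectrum
    match tables through quality filtering, target-decoy false discovery
    rate control, binomial site-localization scoring, parsimonious protein
    grouping and site-level reporter aggregation; normalizes reporter
    matrices (equal-loading, site-to-protein, median-centering) and ranks
    site abundance by MS1 apportionment; calls differentially regulated
    sites with an S0-modified Welch statistic under permutation-based FDR
    control and, alternatively, with moderated t-statistics under
    Benjamini-Hochberg correction; annotates sites against a mitochondrial
    subcompartment inventory; maps modified lysines between ortholog
    sequences by global alignment to compute cross-species conservation;
    estimates protein copy numbers with the histone proteomic ruler; and
    quantifies ubiquitin chain linkages and phospho-Ser65 stoichiometry
    from heavy-reference (AQUA) peptide measurements. A synthetic-data
    generator with planted ground truth supports calibration and power
    analysis of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    withr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    limma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
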