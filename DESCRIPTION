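Package: b56motif
Title: Discovery and Scoring of PP2A-B56 Docking Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and scoring short linear motifs (SLiMs)
    that dock substrates onto PP2A-B56 (B-prime) holoenzymes. Implements
    processing of proteomic peptide phage display (ProP-PD) sequencing-count
    tables (count cutoffs, promiscuity filtering, motif rescue, set
    overlaps), de novo degenerate consensus discovery from enriched peptide
    sets, proteome scanning for the [LMFI]xx[ILV]xE consensus with N-score
    and anchor-class rules, classification of matches as intrinsic or
    phosphorylation-responsive, Plk1 consensus site prediction, a
    charge-hydropathy disorder heuristic, and quantitative binding models
    (global 1:1 biolayer-interferometry kinetics, single-site isothermal
    titration calorimetry isotherms, and competitive displacement
    equilibria). A synthetic-data module generates tiled phage libraries,
    proteomes with planted ground-truth motifs, overdispersed sequencing
    counts and noisy binding traces so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    deSolve,
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
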