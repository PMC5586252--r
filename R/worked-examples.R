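# Bundled worked-example peptides: reported B56-interaction motifs from
# the mitotic/cytokinetic proteome, with their expected flank statistics,
# used as built-in checks of the scanner and the classification rules.

#' Example intrinsic B56-docking peptides
#'
#' Reported consensus-matching peptides from known or predicted PP2A-B56
#' substrates at mitotic super-complexes, each carrying an intrinsic
#' (acidic-flank) docking motif. `expected_numDE` gives the number of D/E
#' residues at the flank positions 2, 7, 8 and 9 of the consensus window
#' where the reported count follows that convention; rows whose reported
#' count instead includes the invariant E at position 6 carry `NA` (the
#' two conventions cannot both be reproduced; this package counts flanks
#' only, see the vignette).
#'
#' @return A tibble `uniprot`, `gene`, `peptide`, `expected_numDE`.
#' @export
b56_intrinsic_examples <- function() {
  tibble::tribble(
    ~uniprot, ~gene,      ~peptide,          ~expected_numDE,
    "P51532", "SMARCA4",  "RAFLQAILEHEEQD",  2L,
    "P52732", "KIF11",    "LGSLTSIPENVSTH",  NA_integer_,
    "Q08379", "GOLGA2",   "PQPMPSIPEDLESR",  2L,
    "Q13177", "PAK2",     "LKPLPSVPEEKKPR",  NA_integer_,
    "Q14674", "ESPL1",    "PEIMRTIPEEELTD",  NA_integer_,
    "Q16589", "CCNG2",    "VPELPTIPEGGCFD",  NA_integer_,
    "Q5VT06", "CEP350",   "RGSLESIAEHVDAS",  2L,
    "Q92974", "ARHGEF2",  "FTRMQDIPEETESR",  2L,
    "Q9Y2I6", "NLP",      "AERLQAIQEERARS",  NA_integer_,
    "Q9Y2T1", "AXIN2",    "CGYLPTLNEEEEWT",  3L
  )
}

#' Example phosphorylation-responsive B56-docking peptides
#'
#' Reported consensus-matching peptides whose docking depends on
#' phosphorylation of flank serines/threonines, with the expected S/T
#' flank positions (among motif positions 2, 7, 8, 9).
#'
#' @return A tibble `uniprot`, `gene`, `peptide`, `expected_st_positions`
#'   (list column of integer flank positions).
#' @export
b56_phospho_examples <- function() {
  tibble::tribble(
    ~uniprot, ~gene,      ~peptide,          ~expected_st_positions,
    "Q9C0D2", "CEP295",   "SSSLSQVDESERFQ",  list(c(2L, 7L)),
    "Q9C0D2", "CEP295b",  "TKKLSQLGESELFA",  list(c(2L, 7L)),
    "Q9H1A4", "ANAPC1",   "VVLLSPVPELRDSS",  list(2L),
    "O95835", "LATS1",    "RQMLQEIRESLRNL",  list(7L),
    "Q99996", "AKAP9",    "NLELQVLLESEKVR",  list(7L),
    "Q08379", "GOLGA2b",  "QEKLSELKETVELK",  list(c(2L, 7L)),
    "Q8NF91", "SYNE1",    "SSDLSTIQERMEEL",  list(2L)
  ) |>
    dplyr::mutate(expected_st_positions =
                    purrr::map(.data$expected_st_positions, 1))
}

#' Bundled reference peptides used in the worked examples
#'
#' The CIP2A docking peptide (residues 713-722 context, peptide-local
#' numbering), the Cyk4 B56-binding region (context peptide numbered from
#' residue 140, motif spanning 143-151) and the three phospho-peptides
#' that test the strict E requirement at motif position 6.
#'
#' @return A named list: `cip2a`, `cyk4`, `cyk4_offset`,
#'   `cyk4_motif_range`, `phospho_peptides`.
#' @export
b56_reference_peptides <- function() {
  list(
    cip2a = "FQHNRKLESVAEEHEI",
    cyk4 = "NKRLSTIDESGSIL",
    cyk4_offset = 140L,
    cyk4_motif_range = c(143L, 151L),
    phospho_peptides = c("LEPVRpSEE", "LEPIRpSEE", "LEPIRpTEE")
  )
}

#' Evaluate the bundled worked examples
#'
#' Runs the scanner, scorer, classifier and Plk1 predictor over the
#' bundled reference peptides and compares each computed quantity to its
#' expected value: the D/E flank counts of the intrinsic examples, the
#' S/T flank positions of the phospho-responsive examples (with CEP295
#' classified phospho-responsive), the three acidic flanks of the CIP2A
#' window, the unique Plk1 site at Cyk4 S149, and the zero matches of the
#' phospho-position-6 peptides.
#'
#' @return A tibble `check`, `expected`, `computed`, `pass`; attribute
#'   `all_pass` summarises the run.
#' @export
report_worked_examples <- function() {
  rows <- list()
  add <- function(check, expected, computed) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      check = check,
      expected = as.character(expected),
      computed = as.character(computed),
      pass = identical(as.character(expected), as.character(computed))
    )
  }

  intr <- b56_intrinsic_examples()
  for (i in seq_len(nrow(intr))) {
    ex <- intr[i, ]
    if (is.na(ex$expected_numDE)) next
    hits <- find_motif_windows(ex$peptide)
    got <- if (nrow(hits) == 0) NA_integer_ else
      max(purrr::map_int(hits$window,
                         ~ score_window(.x)$numDE))
    add(paste0(ex$gene, " flank D/E count"), ex$expected_numDE, got)
  }
  for (i in seq_len(nrow(b56_phospho_examples()))) {
    ex <- b56_phospho_examples()[i, ]
    hits <- find_motif_windows(ex$peptide)
    got <- if (nrow(hits) == 0) "none" else
      paste(sort(unique(unlist(
        purrr::map(hits$window,
                   ~ score_window(.x)$phospho_positions[[1]])))),
        collapse = ",")
    add(paste0(ex$gene, " flank S/T positions"),
        paste(ex$expected_st_positions[[1]], collapse = ","), got)
  }
  # CEP295 classification
  cep295 <- find_motif_windows("SSSLSQVDESERFQ")$window[1]
  sc <- score_window(cep295)
  ac <- anchor_class(cep295)
  add("CEP295 classification", "phospho_responsive",
      classify_match(sc$N, sc$N_intrinsic, ac$min_N))
  # CIP2A: one window, three acidic flanks
  ref <- b56_reference_peptides()
  cip <- find_motif_windows(ref$cip2a)
  add("CIP2A window count", 1L, nrow(cip))
  add("CIP2A flank D/E count", 3L,
      if (nrow(cip) > 0) score_window(cip$window[1])$numDE else NA)
  # Cyk4 Plk1 site
  plk <- predict_plk1_sites(ref$cyk4, offset = ref$cyk4_offset)
  in_motif <- plk$position[plk$position >= ref$cyk4_motif_range[1] &
                             plk$position <= ref$cyk4_motif_range[2]]
  add("Cyk4 Plk1 site in motif", 149L,
      if (length(in_motif) == 1) in_motif else
        paste(in_motif, collapse = ","))
  # strict E at position 6
  for (p in ref$phospho_peptides) {
    add(paste0(p, " match count"), 0L, nrow(find_motif_windows(p)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "all_pass") <- all(out$pass)
  out
}
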