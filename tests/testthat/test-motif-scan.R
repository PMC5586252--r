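test_that("window finding reports all overlapping consensus matches", {
  hits <- find_motif_windows("FQHNRKLESVAEEHEI")
  expect_equal(hits$start, 7L)
  expect_equal(hits$window, "LESVAEEHE")

  expect_equal(nrow(find_motif_windows("")), 0)
  expect_equal(nrow(find_motif_windows("LAAIAE")), 0)  # too short

  # two overlapping windows
  two <- find_motif_windows("LAAIAEAAALAAIAEAAA")
  expect_equal(two$start, c(1L, 10L))
})

test_that("phosphorylated or substituted position 6 never matches", {
  for (p in c("LEPVRpSEE", "LEPIRpSEE", "LEPIRpTEE")) {
    expect_equal(nrow(find_motif_windows(p)), 0)
  }
  # D for E at position 6 (the non-substitutable anchor)
  expect_equal(nrow(find_motif_windows("LAAIADAAA")), 0)
  # but a phospho-mark at a flank position still matches
  marked <- find_motif_windows("LpSAIAEAAA")
  expect_equal(marked$start, 1L)
  expect_equal(marked$window, "LSAIAEAAA")
})

test_that("windows with non-standard residues are skipped", {
  expect_equal(nrow(find_motif_windows("LAXIAEAAA")), 0)
  expect_equal(nrow(find_motif_windows("LAAIAEAAB")), 0)
  # a clean window elsewhere in the same sequence still matches
  hits <- find_motif_windows("XXXXLAAIAEAAA")
  expect_equal(hits$start, 5L)
})

test_that("scanner agrees with a regex-lookahead oracle on random sequences", {
  withr::with_seed(42, {
    for (i in 1:300) {
      s <- random_seq(sample(9:60, 1))
      expect_identical(find_motif_windows(s)$start,
                       oracle_consensus_starts(s))
    }
  })
})

test_that("flank scoring counts positions 2, 7, 8, 9 only", {
  sc <- score_window("LESIAEHVD")  # CEP350 window
  expect_equal(sc$numDE, 2L)
  expect_equal(sc$numST, 0L)
  expect_equal(sc$N, 2L)

  expect_equal(score_window("LESVAEEHE")$numDE, 3L)  # CIP2A window

  z <- score_window("LAAIAEAAA")
  expect_equal(unlist(z[c("numDE", "numST", "numKR", "N")]),
               c(numDE = 0L, numST = 0L, numKR = 0L, N = 0L))

  neg <- score_window("LKAIAEAKK")
  expect_equal(neg$numKR, 3L)
  expect_equal(neg$N, -3L)

  # acidic residues at non-flank positions 3 and 5 do not count
  expect_equal(score_window("LAEIEEAAA")$numDE, 0L)
  expect_error(score_window("LESIAE"), "9 residues")
})

test_that("score identity and range hold on random consensus windows", {
  withr::with_seed(7, {
    for (i in 1:200) {
      w <- paste0(sample(c("L", "M", "F", "I"), 1), random_seq(2),
                  sample(c("I", "L", "V"), 1), random_seq(1), "E",
                  random_seq(3))
      sc <- score_window(w)
      expect_equal(sc$N, sc$numDE + sc$numST - sc$numKR)
      expect_true(sc$N >= -4 && sc$N <= 4)
      expect_lte(sc$N_intrinsic, sc$N)
    }
  })
})

test_that("anchor classes map to minimum N of 1, 2 and 4", {
  expect_equal(anchor_class("LAAIAEAAA")$min_N, 1L)
  expect_equal(anchor_class("LAAVAEAAA")$min_N, 2L)
  expect_equal(anchor_class("MAAIAEAAA")$min_N, 2L)
  expect_equal(anchor_class("MAAVAEAAA")$min_N, 4L)
  expect_equal(anchor_class("FAALAEAAA")$anchor_class, "both_similar")
})

test_that("classification follows the intrinsic / phospho-responsive rule", {
  # CEP350: N_intrinsic = 2 >= min_N = 1 -> intrinsic
  sc <- score_window("LESIAEHVD"); ac <- anchor_class("LESIAEHVD")
  expect_equal(classify_match(sc$N, sc$N_intrinsic, ac$min_N), "intrinsic")
  # CEP295: S/T carries it over the threshold -> phospho-responsive
  sc <- score_window("LSQVDESER"); ac <- anchor_class("LSQVDESER")
  expect_equal(sc$numDE, 1L); expect_equal(sc$numST, 2L)
  expect_equal(sc$numKR, 1L)
  expect_equal(ac$min_N, 2L)
  expect_equal(classify_match(sc$N, sc$N_intrinsic, ac$min_N),
               "phospho_responsive")
  expect_equal(sc$phospho_positions[[1]], c(2L, 7L))
  # nothing at the flanks -> fail
  sc <- score_window("LAAIAEAAA"); ac <- anchor_class("LAAIAEAAA")
  expect_equal(classify_match(sc$N, sc$N_intrinsic, ac$min_N), "fail")
})

test_that("classification is monotone under flank substitutions", {
  rank <- c(fail = 0, phospho_responsive = 1, intrinsic = 2)
  classify_window <- function(w) {
    sc <- score_window(w); ac <- anchor_class(w)
    classify_match(sc$N, sc$N_intrinsic, ac$min_N)
  }
  withr::with_seed(11, {
    for (i in 1:100) {
      w <- strsplit(paste0(sample(c("L", "M", "F", "I"), 1), random_seq(2),
                           sample(c("I", "L", "V"), 1), random_seq(1), "E",
                           random_seq(3)), "")[[1]]
      base <- rank[classify_window(paste(w, collapse = ""))]
      flanks <- c(2, 7, 8, 9)
      # K/R -> A never demotes
      w2 <- w
      w2[flanks][w2[flanks] %in% c("K", "R")] <- "A"
      expect_gte(rank[classify_window(paste(w2, collapse = ""))], base)
      # A -> E never demotes
      w3 <- w
      w3[flanks][w3[flanks] == "A"] <- "E"
      expect_gte(rank[classify_window(paste(w3, collapse = ""))], base)
    }
  })
})

test_that("Plk1 site prediction equals brute-force enumeration", {
  hits <- predict_plk1_sites("NKRLSTIDESGSIL", offset = 140L)
  expect_equal(hits$position, 149L)
  expect_equal(hits$minus2, "D")
  expect_equal(nrow(predict_plk1_sites("AAAAAA")), 0)
  expect_equal(predict_plk1_sites("ADASDNTA")$position, c(4L, 7L))
  withr::with_seed(5, {
    for (i in 1:200) {
      s <- random_seq(sample(3:50, 1))
      expect_identical(predict_plk1_sites(s)$position, oracle_plk1(s))
    }
  })
})

test_that("disorder heuristic signs poly-E disordered and poly-L ordered", {
  e <- disorder_profile(strrep("E", 40))
  l <- disorder_profile(strrep("L", 40))
  expect_true(all(e > 0))
  expect_true(all(l < 0))
  withr::with_seed(3, {
    for (i in 1:20) {
      s <- random_seq(sample(1:80, 1))
      expect_length(disorder_profile(s), nchar(s))
    }
  })
  ext <- disorder_profile("PEPTIDE", method = "external_scores",
                          scores = seq(0.1, 0.7, by = 0.1))
  expect_equal(ext, seq(0.1, 0.7, by = 0.1))
  expect_error(disorder_profile("PEPTIDE", method = "external_scores",
                                scores = c(1, 2)), "cover")
})

test_that("proteome scan recovers planted windows with class and N", {
  proteome <- generate_background_proteome(60, c(80, 150), seed = 21)
  planted <- plant_motifs(proteome, default_plant_specs(12, 6, 6),
                          seed = 22)
  cand <- scan_proteome(planted$proteins, disorder = "off")
  truth <- planted$truth
  pos <- dplyr::inner_join(truth[truth$target_class != "decoy", ], cand,
                           by = c("protein", "start"))
  expect_equal(nrow(pos), 18)
  expect_equal(pos$class, pos$target_class)
  expect_equal(pos$N, pos$target_N)
  leak <- dplyr::inner_join(truth[truth$target_class == "decoy", ], cand,
                            by = c("protein", "start"))
  expect_equal(nrow(leak), 0)
})

test_that("scan modes, annotations and degenerate inputs behave", {
  empty <- scan_proteome(tibble::tibble(protein = character(0),
                                        sequence = character(0)))
  expect_equal(nrow(empty), 0)

  # consensus-only keeps sub-threshold windows that n-rule drops
  prot <- c(p1 = "AAALAAIAEAAAAA")  # N = 0 window
  expect_equal(nrow(scan_proteome(prot, mode = "n-rule")), 0)
  co <- scan_proteome(prot, mode = "consensus-only")
  expect_equal(nrow(co), 1)
  expect_equal(co$class, "fail")

  # every bundled intrinsic example yields a consensus window
  ex <- b56_intrinsic_examples()
  rows <- scan_proteome(
    tibble::tibble(protein = ex$gene, sequence = ex$peptide),
    mode = "consensus-only", disorder = "off")
  expect_true(all(ex$gene %in% rows$protein))

  # annotation joins
  prot2 <- c(p2 = "AAALESIAEHVDAA")  # window starts at 4
  ann <- scan_proteome(
    prot2, disorder = "off",
    phosphosites = tibble::tibble(protein = "p2",
                                  position = c(5L, 6L, 12L),
                                  residue = c("E", "S", "D")),
    locations = tibble::tibble(protein = "p2",
                               location = c("midbody", "centrosome")))
  expect_equal(ann$known_phosphosites[[1]], c(5L, 12L))  # flanks 2, 9
  expect_equal(ann$locations[[1]], c("centrosome", "midbody"))
  expect_error(
    scan_proteome(prot2,
                  locations = tibble::tibble(protein = "p2",
                                             location = "nucleus")),
    "unknown locations")

  # hard disorder filter drops ordered contexts
  ordered_ctx <- c(p3 = paste0(strrep("L", 30), "LESIAEHVD",
                               strrep("L", 30)))
  expect_equal(nrow(scan_proteome(ordered_ctx, disorder = "builtin",
                                  min_disorder = 0)), 0)
  expect_equal(nrow(scan_proteome(ordered_ctx, disorder = "off")), 1)
})

test_that("phospho-mark parsing validates its grammar", {
  expect_equal(parse_peptide("LEPVRpSEE")$residues,
               strsplit("LEPVRSEE", "")[[1]])
  expect_equal(which(parse_peptide("LEPVRpSEE")$phospho), 6L)
  expect_error(parse_peptide("ApA"), "phospho mark")
  expect_error(parse_peptide("AAp"), "phospho mark")
  expect_equal(strip_phospho_marks(c("pSAA", "AA")), c("SAA", "AA"))
})
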