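test_that("background proteome generation is deterministic and well-formed", {
  expect_equal(nrow(generate_background_proteome(0, c(10, 20), seed = 1)), 0)

  a <- generate_background_proteome(5, c(50, 50), seed = 7)
  b <- generate_background_proteome(5, c(50, 50), seed = 7)
  expect_identical(a, b)
  expect_true(all(a$length == 50))
  expect_true(all(strsplit(paste(a$sequence, collapse = ""), "")[[1]] %in%
                    AA))

  expect_error(generate_background_proteome(2, c(10, 20),
                                            aa_freqs = rep(0.1, 20)),
               "sum to 1")
})

test_that("sampled residue frequencies match the background simplex", {
  pr <- generate_background_proteome(1000, c(100, 300), seed = 3)
  res <- strsplit(paste(pr$sequence, collapse = ""), "")[[1]]
  n <- length(res)
  freqs <- table(factor(res, levels = AA)) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freqs - 0.05) < 3 * se))
})

test_that("planted windows are retrievable, conformant and scored exactly", {
  pr <- generate_background_proteome(40, c(60, 120), seed = 9)
  specs <- dplyr::bind_rows(
    plant_spec("intrinsic", "L", "I", 2L, 8),
    plant_spec("intrinsic", "M", "V", 4L, 3),
    plant_spec("phospho_responsive", "L", "V", 2L, 5),
    plant_spec("decoy", "L", "I", 2L, 4)
  )
  planted <- plant_motifs(pr, specs, seed = 10)
  truth <- planted$truth
  expect_equal(nrow(truth), 20)
  for (i in seq_len(nrow(truth))) {
    seqi <- planted$proteins$sequence[planted$proteins$protein ==
                                        truth$protein[i]]
    expect_equal(unname(substring(seqi, truth$start[i],
                                  truth$start[i] + 8)),
                 truth$window[i])
    in_range <- truth$start[i] >= 1 &&
      truth$start[i] + 8 <= nchar(seqi)
    expect_true(in_range)
    if (truth$target_class[i] == "decoy") {
      # violates exactly the position-6 constraint
      expect_equal(nrow(find_motif_windows(truth$window[i])), 0)
      w6 <- substring(truth$window[i], 6, 6)
      expect_equal(w6, "D")
      fixed <- truth$window[i]
      substr(fixed, 6, 6) <- "E"
      expect_equal(nrow(find_motif_windows(fixed)), 1)
    } else {
      expect_equal(nrow(find_motif_windows(truth$window[i])), 1)
      expect_equal(score_window(truth$window[i])$N, truth$target_N[i])
    }
  }
  expect_error(plant_spec("intrinsic", "M", "V", 2L),
               "anchor-class minimum")
  expect_error(
    plant_motifs(generate_background_proteome(1, c(20, 20), seed = 1),
                 plant_spec("intrinsic", count = 10), seed = 2),
    "insufficient room")
})

test_that("tiling arithmetic covers every protein as configured", {
  tl <- tile_library(c(p = strrep("A", 25)), 16, 7)
  expect_equal(tl$start, c(1L, 10L))
  expect_equal(nchar(tl$peptide), c(16L, 16L))

  one <- tile_library(c(p = random_seq(16)), 16, 7)
  expect_equal(nrow(one), 1)

  # short proteins: full-sequence tile or skipped
  expect_equal(tile_library(c(p = "SHORTSEQ"), 16, 7)$peptide, "SHORTSEQ")
  expect_equal(nrow(tile_library(c(p = "SHORTSEQ"), 16, 7,
                                 short = "skip")), 0)

  withr::with_seed(13, {
    for (L in c(17, 30, 47, 100, 161)) {
      s <- random_seq(L)
      tl <- tile_library(c(p = s), 16, 7)
      # adjacent regular tiles overlap exactly 7 residues
      regular <- tl$start[-nrow(tl)]
      if (length(regular) > 1) {
        expect_true(all(diff(regular) == 9))
      }
      # union of tiles covers 1..L and reconstructs the protein
      expect_equal(max(tl$start + nchar(tl$peptide) - 1), L)
      rec <- character(L)
      for (i in seq_len(nrow(tl))) {
        idx <- tl$start[i]:(tl$start[i] + nchar(tl$peptide[i]) - 1)
        rec[idx] <- strsplit(tl$peptide[i], "")[[1]]
      }
      expect_equal(paste(rec, collapse = ""), s)
    }
  })
  expect_error(tile_library(c(p = "AAAA"), 16, 16))
})

test_that("count simulation hits its configured enrichment structure", {
  pr <- generate_background_proteome(120, c(100, 160), seed = 31)
  planted <- plant_motifs(pr, plant_spec("intrinsic", count = 40),
                          seed = 32)
  tiles <- tile_library(planted$proteins)

  # null case: enrichment 1 leaves motif tiles indistinguishable
  cfg0 <- count_sim_config(enrichment_factor = 1,
                           promiscuous_fraction = 0, base_mean = 5,
                           seed = 33)
  cn0 <- simulate_phage_counts(tiles, planted$truth, "bait1", cfg0)
  motif0 <- cn0$count[cn0$enriched == "motif"]
  bg0 <- cn0$count[cn0$enriched == "background"]
  p <- stats::wilcox.test(motif0, bg0[seq_len(500)])$p.value
  expect_gt(p, 0.01)

  # strong enrichment: motif tiles clear the background 95th percentile
  cfg <- count_sim_config(enrichment_factor = 20, dispersion = 50,
                          promiscuous_fraction = 0, base_mean = 10,
                          seed = 34)
  cn <- simulate_phage_counts(tiles, planted$truth, "bait1", cfg)
  q95 <- stats::quantile(cn$count[cn$enriched == "background"], 0.95)
  motif_counts <- cn$count[cn$enriched == "motif"]
  expect_gt(length(motif_counts), 10)
  expect_gte(mean(motif_counts > q95), 0.9)

  # promiscuous tiles: binomial expectation over 3 baits
  cfg_p <- count_sim_config(promiscuous_fraction = 0.05, seed = 35)
  tiles1k <- tiles[seq_len(1000), ]
  cn_p <- simulate_phage_counts(tiles1k,
                                planted$truth[0, ],
                                c("b1", "b2", "b3"), cfg_p)
  n_prom <- length(unique(paste(cn_p$protein, cn_p$start)[
    cn_p$enriched == "promiscuous"]))
  expect_lt(abs(n_prom - 50), 3 * sqrt(1000 * 0.05 * 0.95))

  # determinism
  cn_rep <- simulate_phage_counts(tiles1k, planted$truth[0, ],
                                  c("b1", "b2", "b3"), cfg_p)
  expect_identical(cn_p, cn_rep)

  # negative-binomial marginals at n >= 1e4
  big <- simulate_phage_counts(tiles, planted$truth[0, ],
                               c("b1", "b2", "b3", "b4", "b5", "b6", "b7"),
                               count_sim_config(promiscuous_fraction = 0,
                                                base_mean = 5,
                                                dispersion = 10,
                                                seed = 36))
  x <- big$count
  expect_gt(length(x), 1e4)
  expect_lt(abs(mean(x) - 5) / 5, 0.05)
  v_expect <- 5 + 25 / 10
  expect_lt(abs(stats::var(x) - v_expect) / v_expect, 0.1)
})

test_that("simulated binding traces obey the 1:1 closed forms", {
  # zero concentration: identically zero association
  tr0 <- simulate_bli_traces(1e5, 1e-2, 1, 0, noise_sd = 0, seed = 1)
  expect_true(all(tr0$response[tr0$phase == "association"] == 0))

  # saturating concentration: plateau -> Rmax
  trs <- simulate_bli_traces(1e5, 1e-2, 1, 1e-3, t_assoc = 2000,
                             noise_sd = 0, seed = 1)
  plateau <- max(trs$response[trs$phase == "association"])
  expect_lt(abs(plateau - 1), 1e-3)

  # C = KD: plateau Rmax / 2
  expect_equal(bli_forward(1e5, 1e-2, 1, C = 1e-7, t = 1e6), 0.5,
               tolerance = 1e-9)

  expect_error(simulate_bli_traces(1e5, 1e-2, 1, -1e-6),
               "non-negative")

  # determinism with noise
  a <- simulate_bli_traces(1e5, 1e-2, 1, c(1e-7, 1e-6), noise_sd = 0.01,
                           seed = 4)
  b <- simulate_bli_traces(1e5, 1e-2, 1, c(1e-7, 1e-6), noise_sd = 0.01,
                           seed = 4)
  expect_identical(a, b)
})
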