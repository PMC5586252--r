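# Synthetic-data generators: background proteomes, planted ground-truth
# motifs, tiled phage libraries, simulated sequencing counts and noisy
# binding traces. Everything is deterministic for a fixed seed.

#' Generate a random background proteome
#'
#' Proteins are i.i.d. residue strings drawn from a background amino-acid
#' frequency vector, emulating the disordered-region sequence space a
#' proteomic phage-display library tiles.
#'
#' @param n_proteins Number of proteins (may be 0).
#' @param length_range Integer vector `c(min, max)` of protein lengths,
#'   sampled uniformly.
#' @param aa_freqs Background frequencies: a non-negative length-20 vector
#'   summing to 1, named by the standard residues. Default uniform.
#' @param seed Integer seed; identical seeds give identical proteomes.
#' @return A tibble with columns `protein`, `sequence`, `length`.
#' @examples
#' generate_background_proteome(3, c(50, 60), seed = 1)
#' @export
generate_background_proteome <- function(n_proteins,
                                         length_range = c(100L, 300L),
                                         aa_freqs = uniform_aa_freqs(),
                                         seed = 1L) {
  stopifnot(n_proteins >= 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  aa_freqs <- check_aa_freqs(aa_freqs)
  if (n_proteins == 0) {
    return(tibble::tibble(protein = character(0), sequence = character(0),
                          length = integer(0)))
  }
  withr::with_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
                 replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = aa_freqs),
            collapse = "")
    }, character(1))
    tibble::tibble(
      protein = sprintf("prot%04d", seq_len(n_proteins)),
      sequence = seqs,
      length = as.integer(lens)
    )
  })
}

#' Specify a family of motif windows to plant
#'
#' @param target_class `"intrinsic"`, `"phospho_responsive"` or `"decoy"`.
#' @param anchor1 Residue at motif position 1, from `{L, M, F, I}`.
#' @param anchor4 Residue at motif position 4, from `{I, L, V}`.
#' @param target_N Integer N-score in `[-4, 4]` the planted window must
#'   score. Intrinsic windows realise it with D/E (and K/R when negative),
#'   phospho-responsive windows with S/T alone (so their intrinsic score
#'   stays below the anchor minimum). Must reach the anchor-class minimum
#'   for non-decoy classes.
#' @param count Number of instances to plant.
#' @return A one-row tibble (a plant spec).
#' @export
plant_spec <- function(target_class = c("intrinsic", "phospho_responsive",
                                        "decoy"),
                       anchor1 = "L", anchor4 = "I",
                       target_N = 2L, count = 1L) {
  target_class <- match.arg(target_class)
  stopifnot(anchor1 %in% c("L", "M", "F", "I"),
            anchor4 %in% c("I", "L", "V"),
            target_N >= -4, target_N <= 4, count >= 1)
  min_n <- anchor_class(paste0(anchor1, "AA", anchor4, "AEAAA"))$min_N
  if (target_class != "decoy" && target_N < min_n) {
    stop("target_N = ", target_N, " below the anchor-class minimum ",
         min_n, " for anchors ", anchor1, "/", anchor4, call. = FALSE)
  }
  if (target_class == "phospho_responsive" && target_N < 1) {
    stop("phospho-responsive plants need target_N >= 1", call. = FALSE)
  }
  tibble::tibble(target_class = target_class, anchor1 = anchor1,
                 anchor4 = anchor4, target_N = as.integer(target_N),
                 count = as.integer(count))
}

# Residues that contribute nothing at flank positions (not D/E/K/R/S/T).
NEUTRAL_AA <- setdiff(AA20, c("D", "E", "K", "R", "S", "T"))

# Build one 9-mer conforming to (or, for decoys, violating exactly one
# constraint of) the consensus, with the requested flank score.
build_planted_window <- function(target_class, anchor1, anchor4, target_N) {
  w <- sample(NEUTRAL_AA, 9, replace = TRUE)
  w[1] <- anchor1
  w[4] <- anchor4
  w[6] <- "E"
  slots <- sample(c(2L, 7L, 8L, 9L))
  k <- abs(target_N)
  if (k > 0) {
    fill <- if (target_N < 0) {
      sample(c("K", "R"), k, replace = TRUE)
    } else if (target_class == "phospho_responsive") {
      sample(c("S", "T"), k, replace = TRUE)
    } else {
      sample(c("D", "E"), k, replace = TRUE)
    }
    w[slots[seq_len(k)]] <- fill
  }
  if (target_class == "decoy") w[6] <- "D"  # the one violated constraint
  paste(w, collapse = "")
}

#' Plant ground-truth motif windows into a proteome
#'
#' Overwrites non-overlapping 9-residue stretches of the supplied proteins
#' with windows built from each [plant_spec()]. Intrinsic and
#' phospho-responsive plants conform to the consensus and score exactly
#' their `target_N`; decoys violate exactly one constraint (D instead of E
#' at position 6) so that rejection by the scanner is attributable.
#'
#' @param proteins Proteome tibble from [generate_background_proteome()].
#' @param specs One or more plant specs, row-bound.
#' @param seed Integer seed.
#' @return A list with `proteins` (modified proteome) and `truth`
#'   (tibble: `protein`, `start`, `window`, `target_class`, `target_N`).
#' @export
plant_motifs <- function(proteins, specs, seed = 1L) {
  proteome <- as_proteome(proteins)
  specs <- tibble::as_tibble(specs)
  total <- sum(specs$count)
  if (total == 0) {
    return(list(proteins = proteome,
                truth = tibble::tibble(protein = character(0),
                                       start = integer(0),
                                       window = character(0),
                                       target_class = character(0),
                                       target_N = integer(0))))
  }
  withr::with_seed(seed, {
    seqs <- stats::setNames(strsplit(proteome$sequence, ""),
                            proteome$protein)
    occupied <- stats::setNames(vector("list", nrow(proteome)),
                                proteome$protein)
    truth <- vector("list", total)
    row <- 1L
    for (i in seq_len(nrow(specs))) {
      for (j in seq_len(specs$count[i])) {
        window <- build_planted_window(specs$target_class[i],
                                       specs$anchor1[i],
                                       specs$anchor4[i],
                                       specs$target_N[i])
        placed <- FALSE
        for (try in seq_len(500L)) {
          pid <- sample(proteome$protein, 1)
          L <- length(seqs[[pid]])
          if (L < 9) next
          s <- sample.int(L - 8L, 1)
          iv <- s:(s + 8L)
          if (length(intersect(iv, occupied[[pid]])) > 0) next
          seqs[[pid]][iv] <- strsplit(window, "")[[1]]
          occupied[[pid]] <- c(occupied[[pid]], iv)
          truth[[row]] <- tibble::tibble(
            protein = pid, start = as.integer(s), window = window,
            target_class = specs$target_class[i],
            target_N = specs$target_N[i]
          )
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("could not place planted window ", row,
               ": insufficient room in proteome", call. = FALSE)
        }
        row <- row + 1L
      }
    }
    proteome$sequence <- vapply(seqs[proteome$protein], paste,
                                character(1), collapse = "")
    proteome$length <- nchar(proteome$sequence)
    list(proteins = proteome, truth = dplyr::bind_rows(truth))
  })
}

#' Tile a proteome into overlapping peptides
#'
#' Emulates a proteomic phage-display library design: each protein is cut
#' into `tile_length`-mers stepping by `tile_length - tile_overlap`
#' residues, and a final tile anchored at `length - tile_length + 1` is
#' added whenever needed so the C-terminus is always covered. Proteins
#' shorter than `tile_length` yield a single full-sequence tile (or are
#' skipped).
#'
#' @param proteins Proteome tibble or named character vector.
#' @param tile_length Peptide length in residues (default 16).
#' @param tile_overlap Overlap between consecutive tiles (default 7).
#' @param short `"full"` (default) emits short proteins as one
#'   full-sequence tile; `"skip"` drops them.
#' @return A tibble with columns `peptide`, `protein`, `start`.
#' @examples
#' tile_library(c(p1 = strrep("A", 25)), 16, 7)
#' @export
tile_library <- function(proteins, tile_length = 16L, tile_overlap = 7L,
                         short = c("full", "skip")) {
  short <- match.arg(short)
  stopifnot(tile_overlap > 0, tile_overlap < tile_length)
  proteome <- as_proteome(proteins)
  step <- tile_length - tile_overlap
  purrr::pmap_dfr(proteome[, c("protein", "sequence")],
    function(protein, sequence) {
      L <- nchar(sequence)
      if (L < tile_length) {
        if (short == "skip") return(NULL)
        return(tibble::tibble(peptide = sequence, protein = protein,
                              start = 1L))
      }
      starts <- seq(1L, L - tile_length + 1L, by = step)
      if (starts[length(starts)] + tile_length - 1L < L) {
        starts <- c(starts, L - tile_length + 1L)
      }
      tibble::tibble(
        peptide = substring(sequence, starts, starts + tile_length - 1L),
        protein = protein,
        start = as.integer(starts)
      )
    })
}

#' Configuration for sequencing-count simulation
#'
#' @param tile_length,tile_overlap Library design (defaults 16 and 7).
#' @param enrichment_factor Mean count multiplier for motif-bearing tiles
#'   in their bait (and for promiscuous tiles in all baits); >= 1.
#' @param dispersion Negative-binomial size parameter; counts have
#'   variance `mu + mu^2 / dispersion`.
#' @param promiscuous_fraction Fraction of tiles enriched in every bait.
#' @param base_mean Mean background count per tile per bait.
#' @param seed Integer seed.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(tile_length = 16L, tile_overlap = 7L,
                             enrichment_factor = 20,
                             dispersion = 10,
                             promiscuous_fraction = 0.05,
                             base_mean = 0.2,
                             seed = 1L) {
  stopifnot(tile_overlap > 0, tile_overlap < tile_length,
            enrichment_factor >= 1, dispersion > 0,
            promiscuous_fraction >= 0, promiscuous_fraction < 1,
            base_mean > 0)
  structure(list(tile_length = tile_length, tile_overlap = tile_overlap,
                 enrichment_factor = enrichment_factor,
                 dispersion = dispersion,
                 promiscuous_fraction = promiscuous_fraction,
                 base_mean = base_mean, seed = seed),
            class = "count_sim_config")
}

#' Simulate bait-wise phage sequencing counts over a tiled library
#'
#' Background tiles draw negative-binomial counts with mean
#' `base_mean`; tiles containing a full planted (non-decoy) motif window
#' are enriched (`enrichment_factor * base_mean`) in one bait assigned to
#' that window; a random `promiscuous_fraction` of tiles is enriched in
#' every bait, emulating the sticky background binders that recur across
#' phage-display selections.
#'
#' @param tiles Tile tibble from [tile_library()].
#' @param truth Truth table from [plant_motifs()] (may have zero rows).
#' @param baits Character vector of bait names (length >= 1).
#' @param config A [count_sim_config()].
#' @return A tibble with columns `peptide`, `protein`, `start`, `bait`,
#'   `count`, `enriched` (`"background"`, `"motif"` or `"promiscuous"`),
#'   one row per tile x bait.
#' @export
simulate_phage_counts <- function(tiles, truth, baits, config) {
  stopifnot(inherits(config, "count_sim_config"), length(baits) >= 1)
  tiles <- tibble::as_tibble(tiles)
  withr::with_seed(config$seed, {
    truth_use <- truth[truth$target_class != "decoy", , drop = FALSE]
    if (nrow(truth_use) > 0) {
      truth_use$bait <- sample(baits, nrow(truth_use), replace = TRUE)
    }
    # a tile is motif-bearing when it contains the full 9-mer window
    tiles$tile_end <- tiles$start + nchar(tiles$peptide) - 1L
    tiles$motif_bait <- NA_character_
    if (nrow(truth_use) > 0) {
      for (k in seq_len(nrow(truth_use))) {
        sel <- tiles$protein == truth_use$protein[k] &
          tiles$start <= truth_use$start[k] &
          tiles$tile_end >= truth_use$start[k] + 8L
        tiles$motif_bait[sel] <- truth_use$bait[k]
      }
    }
    n_tiles <- nrow(tiles)
    tiles$promiscuous <- FALSE
    n_prom <- round(config$promiscuous_fraction * n_tiles)
    if (n_prom > 0) tiles$promiscuous[sample.int(n_tiles, n_prom)] <- TRUE

    out <- tidyr::expand_grid(tiles, bait = baits)
    out$enriched <- dplyr::case_when(
      out$promiscuous ~ "promiscuous",
      !is.na(out$motif_bait) & out$motif_bait == out$bait ~ "motif",
      TRUE ~ "background"
    )
    mu <- ifelse(out$enriched == "background", config$base_mean,
                 config$base_mean * config$enrichment_factor)
    out$count <- stats::rnbinom(nrow(out), mu = mu,
                                size = config$dispersion)
    dplyr::select(out, "peptide", "protein", "start", "bait", "count",
                  "enriched")
  })
}

#' Simulate biolayer-interferometry binding traces
#'
#' Forward-simulates 1:1 Langmuir binding: during association at analyte
#' concentration C the response follows
#' `R(t) = Rmax * C / (C + KD) * (1 - exp(-(kon * C + koff) * t))`, and
#' during dissociation it decays exponentially with rate `koff` from the
#' association end-point. Gaussian noise of standard deviation `noise_sd`
#' is added to every point.
#'
#' @param kon Association rate constant (per molar per second).
#' @param koff Dissociation rate constant (per second).
#' @param rmax Maximal response (sensor units).
#' @param concentrations Analyte concentrations in molar (>= 0; a zero
#'   concentration gives the reference blank trace).
#' @param t_assoc,t_dissoc Phase durations in seconds (defaults 400 and
#'   300, a typical sensor program).
#' @param dt Sampling interval in seconds.
#' @param noise_sd Noise standard deviation (sensor units).
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `response`, `concentration`,
#'   `phase` (`"association"`/`"dissociation"`); time is global, the
#'   dissociation phase starting at `t_assoc`.
#' @export
simulate_bli_traces <- function(kon, koff, rmax, concentrations,
                                t_assoc = 400, t_dissoc = 300, dt = 2,
                                noise_sd = 0, seed = 1L) {
  stopifnot(kon > 0, koff > 0, rmax > 0)
  if (any(concentrations < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  withr::with_seed(seed, {
    purrr::map_dfr(concentrations, function(C) {
      ta <- seq(0, t_assoc, by = dt)
      td <- seq(dt, t_dissoc, by = dt)
      ra <- bli_forward(kon, koff, rmax, C, ta, phase = "association")
      r_end <- ra[length(ra)]
      rd <- r_end * exp(-koff * td)
      tb <- tibble::tibble(
        time = c(ta, t_assoc + td),
        response = c(ra, rd),
        concentration = C,
        phase = rep(c("association", "dissociation"),
                    c(length(ta), length(td)))
      )
      tb$response <- tb$response + stats::rnorm(nrow(tb), 0, noise_sd)
      tb
    })
  })
}
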