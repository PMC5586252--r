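# Consensus scanning, N-scoring and classification of B56-docking windows.

FLANK_POSITIONS <- c(2L, 7L, 8L, 9L)

#' Find consensus motif windows in one sequence
#'
#' Slides the 9-position pattern along the sequence and reports every
#' window (all overlapping matches) whose residues satisfy the per-position
#' constraints. Phospho marks (`"pS"`/`"pT"`) are parsed before matching;
#' a phosphorylated S/T at motif position 6 does not satisfy the strict
#' `{E}` constraint there. Windows containing non-standard residues
#' (B, J, O, U, X, Z) are skipped. Windows that would run past the
#' C-terminus are not emitted.
#'
#' @param sequence A single protein or peptide string (uppercase, optional
#'   phospho marks).
#' @param pattern A [motif_pattern()].
#' @return A tibble with columns `start` (1-based residue index of motif
#'   position 1, counted in residues after mark parsing) and `window`
#'   (the plain 9-residue window).
#' @examples
#' find_motif_windows("FQHNRKLESVAEEHEI")
#' @export
find_motif_windows <- function(sequence, pattern = motif_pattern()) {
  stopifnot(inherits(pattern, "motif_pattern"))
  parsed <- parse_peptide(sequence)
  r <- parsed$residues
  L <- length(r)
  if (L < 9) {
    return(tibble::tibble(start = integer(0), window = character(0)))
  }
  starts <- seq_len(L - 8L)
  ok <- rep(TRUE, length(starts))
  for (p in 1:9) {
    ok <- ok & r[starts + p - 1L] %in% pattern[[p]]
  }
  starts <- starts[ok]
  windows <- vapply(starts,
                    function(s) paste(r[s:(s + 8L)], collapse = ""),
                    character(1))
  tibble::tibble(start = as.integer(starts), window = windows)
}

#' Score a 9-residue window by its flank composition
#'
#' Counts, over the flank positions 2, 7, 8 and 9 only, the number of
#' acidic residues (D/E), phosphorylatable residues (S/T) and basic
#' residues (K/R). Each flank residue contributes to exactly one counter.
#' The N-score is `N = numDE + numST - numKR` (phospho-inclusive) and the
#' intrinsic score is `N_intrinsic = numDE - numKR` (acidic residues
#' alone). Phosphorylated S/T written as `"pS"`/`"pT"` count toward
#' `numST` like any S/T.
#'
#' @param window A 9-residue window string (optionally with phospho marks).
#' @return A one-row tibble with `numDE`, `numST`, `numKR`, `N`,
#'   `N_intrinsic` and `phospho_positions` (list column: the flank
#'   positions among 2, 7, 8, 9 occupied by S/T).
#' @examples
#' score_window("LESVAEEHE")
#' @export
score_window <- function(window) {
  parsed <- parse_peptide(window)
  r <- parsed$residues
  if (length(r) != 9L) {
    stop("window must contain exactly 9 residues, got ", length(r),
         call. = FALSE)
  }
  flank <- r[FLANK_POSITIONS]
  numDE <- sum(flank %in% c("D", "E"))
  numST <- sum(flank %in% c("S", "T"))
  numKR <- sum(flank %in% c("K", "R"))
  tibble::tibble(
    numDE = numDE,
    numST = numST,
    numKR = numKR,
    N = numDE + numST - numKR,
    N_intrinsic = numDE - numKR,
    phospho_positions = list(FLANK_POSITIONS[flank %in% c("S", "T")])
  )
}

#' Anchor class and minimum N of a consensus window
#'
#' The best anchor residues are L at position 1 and I at position 4;
#' M, F, I at position 1 and L, V at position 4 are the similar
#' (affinity-reducing) substitutes. The minimum N-score a window must
#' reach depends on how many anchors are substituted: 1 when both anchors
#' are best, 2 when one is similar, 4 when both are similar.
#'
#' @param window A 9-residue window string matching the consensus.
#' @return A one-row tibble with `anchor_class` (`"best_best"`,
#'   `"one_similar"` or `"both_similar"`) and `min_N`.
#' @examples
#' anchor_class("LESVAEEHE")
#' @export
anchor_class <- function(window) {
  r <- parse_peptide(window)$residues
  if (length(r) != 9L) {
    stop("window must contain exactly 9 residues", call. = FALSE)
  }
  n_similar <- (r[1] != "L") + (r[4] != "I")
  cls <- c("best_best", "one_similar", "both_similar")[n_similar + 1L]
  tibble::tibble(anchor_class = cls, min_N = c(1L, 2L, 4L)[n_similar + 1L])
}

#' Classify a scored motif window
#'
#' A window is an intrinsic motif when its acidic flanks alone reach the
#' anchor-class minimum (`N_intrinsic >= min_N`); otherwise it is
#' phosphorylation-responsive when counting flank S/T closes the gap
#' (`N >= min_N`), i.e. the site would pass upon phosphorylation of its
#' flank serines/threonines; otherwise it fails.
#'
#' @param N,N_intrinsic,min_N Integer scores as produced by
#'   [score_window()] and [anchor_class()].
#' @return `"intrinsic"`, `"phospho_responsive"` or `"fail"`.
#' @examples
#' classify_match(N = 2, N_intrinsic = 0, min_N = 2)
#' @export
classify_match <- function(N, N_intrinsic, min_N) {
  dplyr::case_when(
    N_intrinsic >= min_N ~ "intrinsic",
    N >= min_N ~ "phospho_responsive",
    TRUE ~ "fail"
  )
}

#' Predict Plk1 consensus sites
#'
#' Plk1 phosphorylates serine/threonine residues that carry D, E or N two
#' residues upstream (the -2 position). The first two residues of the
#' supplied sequence have no -2 context and are never called.
#'
#' @param sequence Protein or peptide string.
#' @param offset Residue number of the first residue of `sequence` in the
#'   numbering to report (default 1).
#' @return A tibble with `position` (in the supplied numbering),
#'   `residue` (S or T) and `minus2` (the residue at -2), sorted by
#'   position.
#' @examples
#' predict_plk1_sites("NKRLSTIDESGSIL", offset = 140)
#' @export
predict_plk1_sites <- function(sequence, offset = 1L) {
  r <- parse_peptide(sequence)$residues
  L <- length(r)
  empty <- tibble::tibble(position = integer(0), residue = character(0),
                          minus2 = character(0))
  if (L < 3) return(empty)
  i <- 3:L
  hit <- r[i] %in% c("S", "T") & r[i - 2L] %in% c("D", "E", "N")
  i <- i[hit]
  tibble::tibble(
    position = as.integer(i + offset - 1L),
    residue = r[i],
    minus2 = r[i - 2L]
  )
}

#' Per-residue intrinsic disorder profile
#'
#' The builtin heuristic is a windowed charge-hydropathy score of the
#' FoldIndex form: over a sliding window (width `2 * window_half_width + 1`,
#' truncated at the termini) it computes
#' `2.785 * <hydropathy> - |<net charge>| - 1.151`, with Kyte-Doolittle
#' hydropathy rescaled to `[0, 1]`, and flips the sign so that larger
#' values mean more disordered. Alternatively an externally computed
#' per-residue score vector (e.g. from a dedicated disorder predictor) can
#' be passed through unchanged.
#'
#' @param sequence Protein string.
#' @param method `"builtin_heuristic"` or `"external_scores"`.
#' @param window_half_width Half-width of the sliding window (default 10,
#'   i.e. a 21-residue window).
#' @param scores Numeric per-residue scores, required (and must cover the
#'   whole sequence) when `method = "external_scores"`.
#' @return Numeric vector, one score per residue.
#' @examples
#' disorder_profile(strrep("E", 30))[15]
#' @export
disorder_profile <- function(sequence,
                             method = c("builtin_heuristic",
                                        "external_scores"),
                             window_half_width = 10L,
                             scores = NULL) {
  method <- match.arg(method)
  r <- parse_peptide(sequence)$residues
  L <- length(r)
  if (method == "external_scores") {
    if (is.null(scores) || length(scores) < L || anyNA(scores[seq_len(L)])) {
      stop("external disorder scores must cover every residue",
           call. = FALSE)
    }
    return(as.numeric(scores[seq_len(L)]))
  }
  if (L == 0) return(numeric(0))
  hyd <- unname((KD_HYDROPATHY[r] + 4.5) / 9)
  chg <- unname(AA_CHARGE[r])
  chg[is.na(chg)] <- 0
  hyd[is.na(hyd)] <- mean(hyd, na.rm = TRUE)  # non-standard residues
  vapply(seq_len(L), function(i) {
    w <- max(1L, i - window_half_width):min(L, i + window_half_width)
    fold <- 2.785 * mean(hyd[w]) - abs(mean(chg[w])) - 1.151
    -fold
  }, numeric(1))
}

#' Scan a proteome for B56-docking candidates
#'
#' Composes window finding, N-scoring, anchor classification and
#' intrinsic/phospho-responsive classification over every protein, then
#' annotates each match with mean window disorder, known phosphosites
#' overlapping the flank positions, and protein locations at cellular
#' super-complexes. Two modes: `"consensus-only"` reports every consensus
#' window regardless of N (classification is still computed), while
#' `"n-rule"` keeps only windows passing their anchor-class minimum N
#' (intrinsic or phospho-responsive).
#'
#' @param proteins Proteome: a tibble with columns `protein`, `sequence`,
#'   or a named character vector.
#' @param pattern A [motif_pattern()].
#' @param mode `"n-rule"` (default) or `"consensus-only"`.
#' @param disorder `"builtin"`, `"external"` or `"off"`. When not off,
#'   each match gains a `disorder_mean` over its 9 residues.
#' @param min_disorder Optional hard filter: drop matches with
#'   `disorder_mean` below this. Default `NULL` (annotate only).
#' @param phosphosites Optional tibble of known phosphosites with columns
#'   `protein`, `position`, `residue`.
#' @param locations Optional tibble with columns `protein`, `location`;
#'   locations must come from the controlled vocabulary kinetochore,
#'   telomere, spindle, centrosome, midbody.
#' @param disorder_scores Optional tibble with columns `protein`,
#'   `position`, `score`, required for `disorder = "external"`.
#' @return A tibble, one row per surviving match, sorted by
#'   `(protein, start)`, with columns `protein`, `start`, `window`,
#'   `anchor_class`, `min_N`, `numDE`, `numST`, `numKR`, `N_intrinsic`,
#'   `N`, `class`, `phospho_positions` (list), `disorder_mean`,
#'   `known_phosphosites` (list), `locations` (list).
#' @export
scan_proteome <- function(proteins,
                          pattern = motif_pattern(),
                          mode = c("n-rule", "consensus-only"),
                          disorder = c("builtin", "external", "off"),
                          min_disorder = NULL,
                          phosphosites = NULL,
                          locations = NULL,
                          disorder_scores = NULL) {
  mode <- match.arg(mode)
  disorder <- match.arg(disorder)
  proteome <- as_proteome(proteins)
  loc_vocab <- c("kinetochore", "telomere", "spindle", "centrosome",
                 "midbody")
  if (!is.null(locations)) {
    stopifnot(all(c("protein", "location") %in% names(locations)))
    bad <- setdiff(unique(locations$location), loc_vocab)
    if (length(bad) > 0) {
      stop("unknown locations: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  if (!is.null(phosphosites)) {
    stopifnot(all(c("protein", "position") %in% names(phosphosites)))
  }

  rows <- purrr::pmap(proteome, function(protein, sequence) {
    hits <- find_motif_windows(sequence, pattern)
    if (nrow(hits) == 0) return(NULL)
    scored <- dplyr::bind_cols(
      hits,
      purrr::map_dfr(hits$window, score_window),
      purrr::map_dfr(hits$window, anchor_class)
    )
    scored$class <- classify_match(scored$N, scored$N_intrinsic,
                                   scored$min_N)
    if (disorder != "off") {
      prof <- switch(disorder,
        builtin = disorder_profile(sequence),
        external = {
          if (is.null(disorder_scores)) {
            stop("disorder = 'external' requires disorder_scores",
                 call. = FALSE)
          }
          sc <- disorder_scores[disorder_scores$protein == protein, ]
          sc <- sc[order(sc$position), ]
          L <- length(parse_peptide(sequence)$residues)
          if (nrow(sc) < L || !all(seq_len(L) %in% sc$position)) {
            stop("external disorder scores missing residues for ", protein,
                 call. = FALSE)
          }
          sc$score[match(seq_len(L), sc$position)]
        })
      scored$disorder_mean <- vapply(scored$start, function(s) {
        mean(prof[s:(s + 8L)])
      }, numeric(1))
    } else {
      scored$disorder_mean <- NA_real_
    }
    scored$protein <- protein
    scored
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      protein = character(0), start = integer(0), window = character(0),
      anchor_class = character(0), min_N = integer(0), numDE = integer(0),
      numST = integer(0), numKR = integer(0), N_intrinsic = integer(0),
      N = integer(0), class = character(0), phospho_positions = list(),
      disorder_mean = numeric(0), known_phosphosites = list(),
      locations = list()
    ))
  }
  if (mode == "n-rule") {
    out <- dplyr::filter(out, .data$class != "fail")
  }
  if (!is.null(min_disorder) && disorder != "off") {
    out <- dplyr::filter(out, .data$disorder_mean >= min_disorder)
  }
  # annotation joins
  out$known_phosphosites <- purrr::map2(out$protein, out$start,
    function(pr, s) {
      if (is.null(phosphosites)) return(integer(0))
      flank_abs <- s + FLANK_POSITIONS - 1L
      ph <- phosphosites[phosphosites$protein == pr, ]
      sort(intersect(ph$position, flank_abs))
    })
  out$locations <- purrr::map(out$protein, function(pr) {
    if (is.null(locations)) return(character(0))
    sort(unique(locations$location[locations$protein == pr]))
  })
  out <- dplyr::arrange(out, .data$protein, .data$start)
  dplyr::select(out, "protein", "start", "window", "anchor_class",
                "min_N", "numDE", "numST", "numKR", "N_intrinsic", "N",
                "class", "phospho_positions", "disorder_mean",
                "known_phosphosites", "locations")
}
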