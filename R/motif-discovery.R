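# De novo discovery of degenerate consensus motifs from enriched peptide
# sets: exhaustive enumeration of short templates with up to 3 defined
# positions over a span of up to 9 residues, binomial overrepresentation
# scoring, and position-frequency-matrix consensus building.

HYDROPHOBIC_CLASS <- c("L", "M", "F", "I", "V")
CLASS_CODE <- "h"  # internal code for the hydrophobic class

# Number of templates in the searched space, for Bonferroni correction:
# defined-position alphabet = 20 residues + 1 class; spacings with span
# <= max_span.
n_templates_total <- function(max_defined = 3L, max_span = 9L) {
  a <- 21
  total <- 0
  if (max_defined >= 1) total <- total + a
  if (max_defined >= 2) total <- total + (max_span - 1) * a^2
  if (max_defined >= 3) {
    total <- total + choose(max_span - 1, 2) * a^3
  }
  total
}

# All template keys present in one peptide (character vector of residues).
# A key is a string over {AA, 'h', '.'}: defined residues at both ends,
# dots between. Fully vectorised over position combinations.
templates_in_peptide <- function(res, max_defined = 3L, max_span = 9L) {
  L <- length(res)
  if (L == 0) return(character(0))
  is_h <- res %in% HYDROPHOBIC_CLASS
  keys <- list()
  # singles
  singles <- unique(res)
  keys[[1]] <- c(singles, if (any(is_h)) CLASS_CODE)
  gap <- function(n) strrep(".", n)
  if (max_defined >= 2 && L >= 2) {
    ij <- which(outer(seq_len(L), seq_len(L),
                      function(i, j) j > i & j - i <= max_span - 1),
                arr.ind = TRUE)
    i <- ij[, 1]; j <- ij[, 2]
    g <- gap(j - i - 1L)
    keys[[2]] <- paste0(res[i], g, res[j])
    if (any(is_h[i])) {
      s <- is_h[i]
      keys[[3]] <- paste0(CLASS_CODE, g[s], res[j][s])
    }
    if (any(is_h[j])) {
      s <- is_h[j]
      keys[[4]] <- paste0(res[i][s], g[s], CLASS_CODE)
    }
    s <- is_h[i] & is_h[j]
    if (any(s)) keys[[5]] <- paste0(CLASS_CODE, g[s], CLASS_CODE)
  }
  if (max_defined >= 3 && L >= 3) {
    trip <- expand.grid(i = seq_len(L), j = seq_len(L), k = seq_len(L))
    trip <- trip[trip$j > trip$i & trip$k > trip$j &
                   trip$k - trip$i <= max_span - 1, , drop = FALSE]
    if (nrow(trip) > 0) {
      i <- trip$i; j <- trip$j; k <- trip$k
      g1 <- gap(j - i - 1L); g2 <- gap(k - j - 1L)
      a <- res[i]; b <- res[j]; cc <- res[k]
      ha <- is_h[i]; hb <- is_h[j]; hc <- is_h[k]
      base <- paste0(a, g1, b, g2, cc)
      more <- character(0)
      for (mask in 1:7) {
        ma <- bitwAnd(mask, 1L) > 0
        mb <- bitwAnd(mask, 2L) > 0
        mc <- bitwAnd(mask, 4L) > 0
        s <- (!ma | ha) & (!mb | hb) & (!mc | hc)
        if (!any(s)) next
        more <- c(more, paste0(
          if (ma) CLASS_CODE else a[s], g1[s],
          if (mb) CLASS_CODE else b[s], g2[s],
          if (mc) CLASS_CODE else cc[s]))
      }
      keys[[6]] <- c(base, more)
    }
  }
  unique(unlist(keys))
}

# Probability that one background position matches a defined symbol.
symbol_prob <- function(sym, background) {
  if (sym == CLASS_CODE) sum(background[HYDROPHOBIC_CLASS])
  else background[[sym]]
}

# Per-window match probability and span of a template key.
template_stats <- function(keys, background) {
  span <- nchar(keys)
  p_match <- vapply(keys, function(k) {
    ch <- strsplit(k, "", fixed = TRUE)[[1]]
    def <- ch[ch != "."]
    prod(vapply(def, symbol_prob, numeric(1), background = background))
  }, numeric(1), USE.NAMES = FALSE)
  list(span = span, p_match = p_match,
       n_defined = vapply(keys, function(k) {
         sum(strsplit(k, "", fixed = TRUE)[[1]] != ".")
       }, integer(1), USE.NAMES = FALSE))
}

# Render an internal key in bracket notation (h -> [LMFIV]).
render_template <- function(keys) {
  stringr::str_replace_all(
    keys, stringr::fixed(CLASS_CODE),
    paste0("[", paste(HYDROPHOBIC_CLASS, collapse = ""), "]"))
}

#' Enumerate overrepresented candidate motifs in a peptide set
#'
#' Exhaustively enumerates degenerate templates with up to `max_defined`
#' defined positions (single residues or the hydrophobic class
#' `[LMFIV]`) spanning at most `max_span` residues, counts for each the
#' number of peptides containing at least one occurrence, and scores
#' overrepresentation with a binomial upper-tail probability given the
#' per-peptide occurrence probability under the background residue
#' frequencies (positions treated as independent). P-values are
#' Bonferroni-corrected over the full enumerated template space (or
#' Benjamini-Hochberg over the observed templates).
#'
#' @param peptides Character vector of >= 5 peptides.
#' @param background Background amino-acid frequencies (default uniform).
#' @param max_defined Maximum number of defined positions (default 3).
#' @param max_span Maximum template span in residues (default 9).
#' @param alpha Significance level applied to the corrected p-value.
#' @param correction `"bonferroni"` (default) or `"BH"`.
#' @return A tibble `pattern`, `span`, `n_defined`, `support`,
#'   `expected`, `p_value`, `p_adj`, `significant`, ranked by corrected
#'   then raw p-value, ties broken by higher support then pattern.
#' @export
enumerate_candidate_motifs <- function(peptides,
                                       background = uniform_aa_freqs(),
                                       max_defined = 3L,
                                       max_span = 9L,
                                       alpha = 0.05,
                                       correction = c("bonferroni", "BH")) {
  correction <- match.arg(correction)
  if (length(peptides) < 5) {
    stop("motif enumeration needs at least 5 peptides", call. = FALSE)
  }
  background <- check_aa_freqs(background)
  parsed <- lapply(peptides, function(p) parse_peptide(p)$residues)
  lens <- lengths(parsed)
  if (any(lens < 1)) stop("empty peptide supplied", call. = FALSE)
  n <- length(peptides)

  per_pep <- lapply(parsed, templates_in_peptide,
                    max_defined = max_defined, max_span = max_span)
  support_tab <- table(unlist(per_pep))
  keys <- names(support_tab)
  support <- as.integer(support_tab)

  st <- template_stats(keys, background)
  # per-peptide occurrence probability: 1 - (1 - p_match)^windows;
  # with mixed peptide lengths the mean over peptides is used.
  p_occ <- vapply(seq_along(keys), function(t) {
    windows <- pmax(lens - st$span[t] + 1L, 0L)
    mean(1 - (1 - st$p_match[t])^windows)
  }, numeric(1))
  p_value <- stats::pbinom(support - 1L, n, p_occ, lower.tail = FALSE)
  p_adj <- if (correction == "bonferroni") {
    pmin(1, p_value * n_templates_total(max_defined, max_span))
  } else {
    stats::p.adjust(p_value, method = "BH")
  }
  out <- tibble::tibble(
    pattern = render_template(keys),
    span = st$span,
    n_defined = st$n_defined,
    support = support,
    expected = n * p_occ,
    p_value = p_value,
    p_adj = p_adj,
    significant = p_adj <= alpha
  )
  dplyr::arrange(out, .data$p_adj, .data$p_value,
                 dplyr::desc(.data$support), .data$pattern)
}

# First occurrence start of an internal-form template in a residue vector,
# or NA. Template given as key string.
template_first_match <- function(res, key) {
  ch <- strsplit(key, "", fixed = TRUE)[[1]]
  span <- length(ch)
  L <- length(res)
  if (L < span) return(NA_integer_)
  def_pos <- which(ch != ".")
  for (s in seq_len(L - span + 1L)) {
    ok <- TRUE
    for (d in def_pos) {
      sym <- ch[d]
      r <- res[s + d - 1L]
      if (sym == CLASS_CODE) {
        if (!r %in% HYDROPHOBIC_CLASS) { ok <- FALSE; break }
      } else if (r != sym) { ok <- FALSE; break }
    }
    if (ok) return(s)
  }
  NA_integer_
}

#' Build a 9-position consensus pattern around a seed motif
#'
#' Aligns the peptides on the first occurrence of the seed template (the
#' 9-position frame starts at the seed's first defined position), builds a
#' position-frequency matrix, and at each position admits the residues
#' whose frequency exceeds `inclusion_threshold` times their background
#' frequency. Positions with no enriched residue become wildcards.
#' Position 6 is forced to `{E}`, and the anchor positions 1 and 4 are
#' restricted to their consensus alphabets (`{L,M,F,I}` and `{I,L,V}`).
#'
#' @param peptides Character vector of peptides.
#' @param seed_pattern Seed template in bracket notation as produced by
#'   [enumerate_candidate_motifs()] (e.g. `"L..I.E"`).
#' @param inclusion_threshold Enrichment ratio (observed/background) a
#'   residue must exceed to be admitted (default 2).
#' @param background Background frequencies (default uniform).
#' @return A [motif_pattern()] with attribute `pfm` (9 x 20 position
#'   frequency matrix) and `n_aligned`.
#' @export
build_consensus <- function(peptides, seed_pattern,
                            inclusion_threshold = 2,
                            background = uniform_aa_freqs()) {
  background <- check_aa_freqs(background)
  key <- stringr::str_replace_all(
    seed_pattern,
    stringr::fixed(paste0("[", paste(HYDROPHOBIC_CLASS, collapse = ""),
                          "]")),
    CLASS_CODE)
  parsed <- lapply(peptides, function(p) parse_peptide(p)$residues)
  starts <- vapply(parsed, template_first_match, integer(1), key = key)
  with_seed <- which(!is.na(starts))
  if (length(with_seed) < 5) {
    stop("seed motif occurs in fewer than 5 peptides", call. = FALSE)
  }
  frames <- list()
  dropped <- 0L
  for (i in with_seed) {
    s <- starts[i]
    if (s + 8L > length(parsed[[i]])) {
      dropped <- dropped + 1L
      next
    }
    frames[[length(frames) + 1L]] <- parsed[[i]][s:(s + 8L)]
  }
  if (dropped > length(with_seed) / 2) {
    stop("alignment frame extends past peptide bounds for >50% of ",
         "seed occurrences", call. = FALSE)
  }
  fm <- do.call(rbind, frames)
  n_aligned <- nrow(fm)
  pfm <- t(apply(fm, 2, function(col) {
    tab <- table(factor(col, levels = AA20))
    as.numeric(tab) / n_aligned
  }))
  colnames(pfm) <- AA20
  allowed <- lapply(1:9, function(p) {
    enriched <- AA20[pfm[p, ] > inclusion_threshold * background[AA20]]
    if (length(enriched) == 0) NULL else enriched
  })
  # enforce the anchor alphabets
  a1 <- intersect(allowed[[1]], c("L", "M", "F", "I"))
  a4 <- intersect(allowed[[4]], c("I", "L", "V"))
  pat <- motif_pattern(list(
    `1` = if (length(a1) > 0) a1 else NULL,
    `2` = allowed[[2]], `3` = allowed[[3]],
    `4` = if (length(a4) > 0) a4 else NULL,
    `5` = allowed[[5]], `6` = "E",
    `7` = allowed[[7]], `8` = allowed[[8]], `9` = allowed[[9]]
  ))
  attr(pat, "pfm") <- pfm
  attr(pat, "n_aligned") <- n_aligned
  pat
}
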