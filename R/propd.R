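# Processing of proteomic peptide phage display (ProP-PD) sequencing-count
# tables: count cutoffs, promiscuity filtering, motif rescue, peptide
# mapping and ligand-set overlaps.

check_count_table <- function(counts) {
  counts <- tibble::as_tibble(counts)
  need <- c("peptide", "bait", "count")
  if (!all(need %in% names(counts))) {
    stop("count table must have columns peptide, bait, count",
         call. = FALSE)
  }
  if (any(counts$count < 0)) {
    stop("negative sequencing counts in input", call. = FALSE)
  }
  counts
}

passes_cutoff <- function(count, cutoff, mode) {
  if (mode == "gt") count > cutoff else count >= cutoff
}

#' Apply a sequencing-count cutoff per bait
#'
#' Retains, for each bait, the peptides whose sequencing count passes the
#' cutoff. With the default `mode = "gt"` a peptide is retained when its
#' count is strictly greater than `cutoff` (so `cutoff = 1` discards
#' singleton reads, which would otherwise make a count cutoff vacuous);
#' `mode = "ge"` retains counts `>= cutoff`.
#'
#' @param counts Tibble with columns `peptide`, `bait`, `count`.
#' @param cutoff Non-negative integer cutoff (default 1).
#' @param mode `"gt"` (strict, default) or `"ge"`.
#' @return A tibble `bait`, `peptide`, `count`, `provenance`
#'   (`"above_cutoff"`), one row per retained bait-peptide pair.
#' @export
apply_count_cutoff <- function(counts, cutoff = 1L,
                               mode = c("gt", "ge")) {
  mode <- match.arg(mode)
  stopifnot(cutoff >= 0)
  counts <- check_count_table(counts)
  counts |>
    dplyr::filter(passes_cutoff(.data$count, cutoff, mode)) |>
    dplyr::mutate(provenance = "above_cutoff") |>
    dplyr::select("bait", "peptide", "count", "provenance") |>
    dplyr::arrange(.data$bait, dplyr::desc(.data$count), .data$peptide)
}

#' Filter out promiscuous peptides
#'
#' A peptide that passes the count cutoff in more than
#' `max_bait_fraction` of the supplied baits is treated as a promiscuous
#' (sticky) binder and removed from every bait, mirroring the removal of
#' ligands that recur across phage-display selections. Promiscuity is
#' judged within the supplied baits.
#'
#' @param counts Tibble with columns `peptide`, `bait`, `count`; needs
#'   at least 2 distinct baits.
#' @param cutoff,mode Cutoff used to decide whether a peptide "occurs" in
#'   a bait (see [apply_count_cutoff()]).
#' @param max_bait_fraction A peptide is retained iff it passes the cutoff
#'   in at most this fraction of baits (default 0.5).
#' @return A list with `counts` (the filtered table, same columns as the
#'   input) and `removed` (character vector of promiscuous peptides).
#' @export
filter_promiscuous <- function(counts, cutoff = 1L, mode = c("gt", "ge"),
                               max_bait_fraction = 0.5) {
  mode <- match.arg(mode)
  counts <- check_count_table(counts)
  n_baits <- dplyr::n_distinct(counts$bait)
  if (n_baits < 2) {
    stop("promiscuity filtering needs at least 2 baits", call. = FALSE)
  }
  occ <- counts |>
    dplyr::filter(passes_cutoff(.data$count, cutoff, mode)) |>
    dplyr::distinct(.data$peptide, .data$bait) |>
    dplyr::count(.data$peptide, name = "n_baits_hit")
  removed <- occ$peptide[occ$n_baits_hit / n_baits > max_bait_fraction]
  list(
    counts = dplyr::filter(counts, !.data$peptide %in% removed),
    removed = sort(removed)
  )
}

#' Rescue below-cutoff peptides containing the consensus motif
#'
#' Peptides whose sequencing counts fall below the cutoff but that contain
#' at least one consensus window are rescued into the ligand set (their
#' provenance marked `"rescued"`), since a genuine docking motif lends
#' them credibility despite shallow sequencing.
#'
#' @param below_cutoff Character vector of below-cutoff peptides (phospho
#'   marks allowed).
#' @param pattern A [motif_pattern()].
#' @return The subset of `below_cutoff` containing >= 1 consensus window.
#' @examples
#' rescue_motif_matches(c("AAAALESVAEEHEAAA", "AAAAAAAAAAAA"))
#' @export
rescue_motif_matches <- function(below_cutoff,
                                 pattern = motif_pattern()) {
  hits <- vapply(below_cutoff, function(p) {
    nrow(find_motif_windows(p, pattern)) > 0
  }, logical(1), USE.NAMES = FALSE)
  below_cutoff[hits]
}

#' Build per-bait ligand sets from a raw count table
#'
#' Composes the full ProP-PD processing chain: promiscuity filtering
#' across baits, count cutoff per bait, and motif rescue of below-cutoff
#' peptides. The result is the reported ligand set: the disjoint union of
#' above-cutoff and rescued peptides.
#'
#' @inheritParams filter_promiscuous
#' @param pattern Consensus pattern used for rescue.
#' @return A tibble `bait`, `peptide`, `count`, `provenance`
#'   (`"above_cutoff"` or `"rescued"`).
#' @export
build_ligand_sets <- function(counts, pattern = motif_pattern(),
                              cutoff = 1L, mode = c("gt", "ge"),
                              max_bait_fraction = 0.5) {
  mode <- match.arg(mode)
  counts <- check_count_table(counts)
  filtered <- filter_promiscuous(counts, cutoff, mode,
                                 max_bait_fraction)$counts
  above <- apply_count_cutoff(filtered, cutoff, mode)
  below <- filtered |>
    dplyr::filter(!passes_cutoff(.data$count, cutoff, mode),
                  .data$count > 0)
  rescued <- below |>
    dplyr::group_by(.data$bait) |>
    dplyr::filter(.data$peptide %in%
                    rescue_motif_matches(.data$peptide, pattern)) |>
    dplyr::ungroup() |>
    dplyr::mutate(provenance = "rescued") |>
    dplyr::select("bait", "peptide", "count", "provenance")
  dplyr::bind_rows(above, rescued) |>
    dplyr::arrange(.data$bait, .data$provenance, .data$peptide)
}

#' Map peptides back onto a proteome by exact match
#'
#' Phospho marks are stripped before matching; every occurrence of each
#' peptide in every protein is reported with its 1-based start. Peptides
#' absent from the proteome yield no rows.
#'
#' @param peptides Character vector of peptides.
#' @param proteins Proteome tibble or named character vector.
#' @return A tibble `peptide`, `protein`, `start`, one row per occurrence.
#' @export
map_peptides <- function(peptides, proteins) {
  proteome <- as_proteome(proteins)
  if (nrow(proteome) == 0) {
    stop("proteome is empty", call. = FALSE)
  }
  plain <- strip_phospho_marks(peptides)
  purrr::map2_dfr(peptides, plain, function(orig, pep) {
    hits <- purrr::pmap_dfr(proteome[, c("protein", "sequence")],
      function(protein, sequence) {
        pos <- gregexpr(pep, sequence, fixed = TRUE)[[1]]
        if (pos[1] == -1) return(NULL)
        tibble::tibble(protein = protein, start = as.integer(pos))
      })
    if (nrow(hits) == 0) return(NULL)
    dplyr::mutate(hits, peptide = orig, .before = 1)
  })
}

#' Cardinalities of all intersection regions of ligand sets
#'
#' Partitions the union of the supplied sets into its disjoint
#' membership regions (one per non-empty subset of baits) and counts each,
#' i.e. the numbers a Venn diagram of the ligand sets displays.
#'
#' @param sets A named list (>= 2 elements) of character vectors.
#' @return A tibble `region` (bait names joined by `"&"`), `baits`
#'   (list column), `count`; the counts of the disjoint regions sum to the
#'   size of the union.
#' @examples
#' overlap_sets(list(A = c("x", "y"), B = c("y", "z")))
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  nm <- names(sets)
  subsets <- utils::combn
  out <- list()
  k <- 1L
  for (size in seq_along(nm)) {
    combos <- utils::combn(nm, size, simplify = FALSE)
    for (cmb in combos) {
      inside <- rowSums(membership[, cmb, drop = FALSE]) == length(cmb)
      outside <- if (length(cmb) == length(nm)) {
        rep(FALSE, length(universe))
      } else {
        rowSums(membership[, setdiff(nm, cmb), drop = FALSE]) > 0
      }
      out[[k]] <- tibble::tibble(
        region = paste(cmb, collapse = "&"),
        baits = list(cmb),
        count = sum(inside & !outside)
      )
      k <- k + 1L
    }
  }
  dplyr::bind_rows(out)
}
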