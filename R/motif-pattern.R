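#' Construct a 9-position degenerate motif pattern
#'
#' The B56-docking consensus is a 9-residue frame, positions numbered 1-9.
#' Positions 1, 4 and 6 are anchors: position 1 admits a subset of
#' `{L, M, F, I}` (best residue L), position 4 a subset of `{I, L, V}`
#' (best residue I), and position 6 is strictly `E` -- neither `D` nor a
#' phosphorylated S/T can substitute for it. The remaining positions
#' (2, 3, 5, 7, 8, 9) are wildcards by default; positions 2, 7, 8 and 9
#' are the charge/phospho "flank" positions used by the N-score.
#'
#' @param positions A list of up to 9 character vectors giving the allowed
#'   residues at each motif position; `NULL` entries (or omitted trailing
#'   positions) are wildcards over the 20 standard residues. The default is
#'   the merged consensus `[LMFI]xx[ILV]xExxx`.
#' @return An object of class `motif_pattern`: a length-9 list of allowed
#'   residue sets.
#' @examples
#' motif_pattern()
#' motif_pattern(list(`1` = "L", `4` = c("I", "V")))
#' @export
motif_pattern <- function(positions = NULL) {
  allowed <- rep(list(AA20), 9)
  allowed[[1]] <- c("L", "M", "F", "I")
  allowed[[4]] <- c("I", "L", "V")
  allowed[[6]] <- "E"
  if (!is.null(positions)) {
    stopifnot(is.list(positions))
    idx <- names(positions)
    if (is.null(idx)) idx <- as.character(seq_along(positions))
    for (k in seq_along(positions)) {
      p <- as.integer(idx[k])
      if (is.na(p) || p < 1 || p > 9) {
        stop("pattern positions must be indexed 1..9", call. = FALSE)
      }
      if (!is.null(positions[[k]])) {
        allowed[[p]] <- unique(toupper(positions[[k]]))
      }
    }
  }
  validate_motif_pattern(allowed)
  structure(allowed, class = "motif_pattern")
}

validate_motif_pattern <- function(allowed) {
  stopifnot(length(allowed) == 9)
  if (!identical(allowed[[6]], "E")) {
    stop("motif position 6 must be exactly {E}", call. = FALSE)
  }
  if (length(allowed[[1]]) == 0 ||
      !all(allowed[[1]] %in% c("L", "M", "F", "I"))) {
    stop("motif position 1 must be a non-empty subset of {L, M, F, I}",
         call. = FALSE)
  }
  if (length(allowed[[4]]) == 0 ||
      !all(allowed[[4]] %in% c("I", "L", "V"))) {
    stop("motif position 4 must be a non-empty subset of {I, L, V}",
         call. = FALSE)
  }
  bad <- !vapply(allowed, function(a) all(a %in% AA20), logical(1))
  if (any(bad)) {
    stop("motif pattern contains non-standard residues", call. = FALSE)
  }
  invisible(allowed)
}

#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(x, function(a) {
    if (length(a) == 20) "x"
    else if (length(a) == 1) a
    else paste0("[", paste(a, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern> ", format(x), "\n", sep = "")
  invisible(x)
}
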