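# Shared constants and sequence helpers.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Kyte-Doolittle hydropathy scale.
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Formal side-chain charge at neutral pH (His treated as neutral).
AA_CHARGE <- c(K = 1, R = 1, D = -1, E = -1)

#' Parse a peptide string with phospho marks
#'
#' Peptides from phage-display or synthetic-peptide tables may carry
#' phosphorylated residues written as `"pS"` or `"pT"` (e.g.
#' `"LEPVRpSEE"`). This parses such a string into one element per residue,
#' with a parallel logical flag marking phosphorylated positions. Any other
#' use of lowercase `"p"` is a format error.
#'
#' @param x A single peptide string, uppercase residues with optional
#'   `"pS"`/`"pT"` marks.
#' @return A list with `residues` (character vector of one-letter codes)
#'   and `phospho` (logical vector of the same length).
#' @examples
#' parse_peptide("LEPVRpSEE")
#' @export
parse_peptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  if (!grepl("p", x, fixed = TRUE)) {  # fast path: no phospho marks
    residues <- strsplit(x, "", fixed = TRUE)[[1]]
    return(list(residues = residues,
                phospho = logical(length(residues))))
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  n <- length(chars)
  residues <- character(0)
  phospho <- logical(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "p") {
      if (i == n || !chars[i + 1L] %in% c("S", "T")) {
        stop("phospho mark 'p' must be followed by S or T in peptide: ", x,
             call. = FALSE)
      }
      residues <- c(residues, chars[i + 1L])
      phospho <- c(phospho, TRUE)
      i <- i + 2L
    } else {
      residues <- c(residues, ch)
      phospho <- c(phospho, FALSE)
      i <- i + 1L
    }
  }
  if (length(residues) == 0L && nzchar(x)) {
    stop("peptide empty after mark parsing: ", x, call. = FALSE)
  }
  list(residues = residues, phospho = phospho)
}

#' Strip phospho marks from peptide strings
#'
#' @param x Character vector of peptides, possibly with `"pS"`/`"pT"` marks.
#' @return Character vector of plain residue strings.
#' @export
strip_phospho_marks <- function(x) {
  vapply(x, function(p) paste(parse_peptide(p)$residues, collapse = ""),
         character(1), USE.NAMES = FALSE)
}

# Coerce a proteome given as a named character vector or a tibble with
# columns protein/sequence into the canonical tibble form.
as_proteome <- function(proteins) {
  if (is.character(proteins)) {
    if (is.null(names(proteins)) && length(proteins) > 0) {
      names(proteins) <- paste0("protein_", seq_along(proteins))
    }
    return(tibble::tibble(protein = names(proteins),
                          sequence = unname(proteins)))
  }
  stopifnot(is.data.frame(proteins))
  if (!all(c("protein", "sequence") %in% names(proteins))) {
    stop("proteome must have columns 'protein' and 'sequence'", call. = FALSE)
  }
  tibble::as_tibble(proteins[, c("protein", "sequence"),
                             drop = FALSE])
}

# Validate a background amino-acid frequency vector (simplex over AA20).
check_aa_freqs <- function(aa_freqs) {
  if (is.null(names(aa_freqs))) {
    if (length(aa_freqs) != 20) {
      stop("aa_freqs must be a length-20 vector over the standard residues",
           call. = FALSE)
    }
    names(aa_freqs) <- AA20
  }
  if (!setequal(names(aa_freqs), AA20)) {
    stop("aa_freqs must be named by the 20 standard amino acids",
         call. = FALSE)
  }
  aa_freqs <- aa_freqs[AA20]
  if (any(aa_freqs < 0) || abs(sum(aa_freqs) - 1) > 1e-8) {
    stop("aa_freqs must be non-negative and sum to 1", call. = FALSE)
  }
  aa_freqs
}

uniform_aa_freqs <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}
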