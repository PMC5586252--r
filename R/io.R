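# Plain-text I/O: FASTA proteomes (via Biostrings) and the TSV tables
# the pipeline persists between stages.

#' Read a proteome from FASTA
#'
#' @param path Path to an (uncompressed) amino-acid FASTA file.
#' @return A tibble `protein`, `sequence`, `length`.
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    sq <- unname(as.character(aa))
    tibble::tibble(
      protein = sub("\\s.*$", "", names(aa)),
      sequence = sq,
      length = nchar(sq)
    )
  } else {
    lines <- readLines(path)
    idx <- grep("^>", lines)
    if (length(idx) == 0) stop("no FASTA records in ", path, call. = FALSE)
    ends <- c(idx[-1] - 1L, length(lines))
    tibble::tibble(
      protein = sub("\\s.*$", "", sub("^>", "", lines[idx])),
      sequence = vapply(seq_along(idx), function(i) {
        paste(lines[(idx[i] + 1L):ends[i]], collapse = "")
      }, character(1))
    ) |>
      dplyr::mutate(length = nchar(.data$sequence))
  }
}

#' Write a proteome to FASTA
#'
#' @param proteins Proteome tibble or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteins, path) {
  proteome <- as_proteome(proteins)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::AAStringSet(
      stats::setNames(proteome$sequence, proteome$protein))
    Biostrings::writeXStringSet(aa, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(proteome))) {
      writeLines(c(paste0(">", proteome$protein[i]),
                   proteome$sequence[i]), con)
    }
  }
  invisible(path)
}

#' Read a peptide-bait count table
#'
#' Expects a TSV with header columns `peptide`, `bait`, `count`.
#'
#' @param path Path to the TSV.
#' @return A validated count tibble.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) {
    stop("count table not found: ", path, call. = FALSE)
  }
  check_count_table(readr::read_tsv(path, show_col_types = FALSE))
}

# Flatten list columns to comma-joined strings for TSV persistence.
flatten_for_tsv <- function(tbl) {
  dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ","), character(1))))
}

#' Write a candidate (or any pipeline) table as TSV
#'
#' List columns (phospho positions, phosphosites, locations) are joined
#' with commas.
#'
#' @param tbl A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_tsv <- function(tbl, path) {
  readr::write_tsv(flatten_for_tsv(tbl), path)
  invisible(path)
}
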