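# Independent oracles and small fixture builders shared across tests.
# These deliberately use different mechanisms from the package internals
# (regex lookahead, explicit enumeration, closed forms) so that agreement
# is informative.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, alphabet = AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Regex-lookahead oracle for the default consensus on plain sequences
# (no phospho marks, standard residues only). Returns match starts.
oracle_consensus_starts <- function(sequence) {
  m <- gregexpr("(?=[LMFI]..[ILV].E...)", sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Brute-force Plk1 -2 rule by explicit position loop.
oracle_plk1 <- function(sequence, offset = 1L) {
  r <- strsplit(sequence, "")[[1]]
  out <- integer(0)
  for (i in seq_along(r)) {
    if (i >= 3 && r[i] %in% c("S", "T") && r[i - 2] %in% c("D", "E", "N")) {
      out <- c(out, i + offset - 1L)
    }
  }
  out
}

# Brute-force support of an internal-form template (e.g. "L..I.E") over a
# peptide set, by regex with the hydrophobic class expanded.
oracle_template_support <- function(peptides, key) {
  re <- gsub("h", "[LMFIV]", key, fixed = TRUE)
  re <- gsub(".", "[A-Z]", re, fixed = TRUE)
  sum(vapply(peptides, function(p) grepl(re, p, perl = TRUE), logical(1)))
}

# Exact closed-form solution of the two-ligand competitive equilibrium
# (cubic in the free receptor concentration), used as the independent
# check of the numerical solver.
oracle_competition_free_receptor <- function(p_tot, a_tot, b_tot,
                                             kd_a, kd_b) {
  a <- kd_a + kd_b + a_tot + b_tot - p_tot
  b <- kd_b * (a_tot - p_tot) + kd_a * (b_tot - p_tot) + kd_a * kd_b
  cc <- -kd_a * kd_b * p_tot
  theta <- acos((-2 * a^3 + 9 * a * b - 27 * cc) /
                  (2 * sqrt((a^2 - 3 * b)^3)))
  -a / 3 + (2 / 3) * sqrt(a^2 - 3 * b) * cos(theta / 3)
}

# Embed the template L..I.E (random residues at the wildcards) at a
# random admissible offset of a random 16-mer.
peptide_with_planted_LxxIxE <- function() {
  p <- strsplit(random_seq(16), "")[[1]]
  s <- sample(1:11, 1)
  p[s] <- "L"; p[s + 3] <- "I"; p[s + 5] <- "E"
  paste(p, collapse = "")
}

default_plant_specs <- function(n_intrinsic = 10, n_phospho = 5,
                                n_decoy = 5) {
  dplyr::bind_rows(
    plant_spec("intrinsic", "L", "I", 2L, n_intrinsic),
    plant_spec("phospho_responsive", "L", "V", 2L, n_phospho),
    plant_spec("decoy", "L", "I", 2L, n_decoy)
  )
}
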