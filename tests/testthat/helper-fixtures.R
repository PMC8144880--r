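# Small in-code fixture builders shared across test files.

AA18 <- c("A", "C", "D", "E", "F", "G", "H", "I", "L",
          "M", "N", "P", "Q", "S", "T", "V", "W", "Y")

# Deterministic unique peptide sequence for index i (valid amino acids,
# tryptic C-terminus), unique up to 18^3 rows.
test_sequence <- function(i) {
  vapply(i, function(k) {
    paste0(AA18[(k %% 18) + 1], AA18[((k %/% 18) %% 18) + 1],
           AA18[((k %/% 324) %% 18) + 1], "GGAK")
  }, character(1))
}

# Peptide matrix from a plain numeric matrix; rows become charge-2
# precursors with deterministic sequences, all mapped to `protein`.
make_pm <- function(m, protein = "P1", sequences = NULL, charges = NULL,
                    proteins = NULL, is_unique = TRUE) {
  m <- as.matrix(m)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(sequences)) sequences <- test_sequence(seq_len(nrow(m)))
  peptide_matrix(m, data.frame(
    peptide_sequence = sequences,
    charge = if (is.null(charges)) 2L else charges,
    protein_id = if (is.null(proteins)) protein else proteins,
    is_unique = is_unique,
    stringsAsFactors = FALSE))
}

# Exactly multiplicative peptide matrix: intensity = truth_s * eff_p,
# with an optional logical mask of present entries.
make_multiplicative_pm <- function(truth, eff, present = NULL,
                                   protein = "P1") {
  m <- outer(eff, truth)
  colnames(m) <- paste0("s", seq_along(truth))
  if (!is.null(present)) m[!present] <- NA_real_
  make_pm(m, protein = protein)
}

# Simple mass-fraction matrix over named proteins.
make_fractions <- function(values, proteins, samples = NULL) {
  m <- as.matrix(values)
  rownames(m) <- proteins
  if (!is.null(samples)) colnames(m) <- samples
  else if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}
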