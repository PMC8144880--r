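#' Peptide-precursor intensity matrix
#'
#' Container pairing a precursors x samples intensity matrix with the
#' precursor annotation (peptide sequence, charge state, parent protein,
#' uniqueness). A precursor is a (peptide sequence, charge) pair -- the
#' analyte actually measured in peptide-centric DIA/SWATH data. Missing
#' intensities are stored as `NA`; a missing entry is a distinct state from
#' zero, and zero intensities are not permitted (an intensity is either
#' observed and strictly positive, or not observed).
#'
#' @param intensities numeric matrix, precursors x samples. `NA` marks a
#'   non-detected precursor; all present values must be > 0.
#' @param peptides data.frame with one row per precursor and columns
#'   `peptide_sequence` (non-empty string over the amino-acid alphabet;
#'   inline modifications are carried opaquely), `charge` (integer >= 1),
#'   `protein_id`, and optionally `is_unique` (defaults to `TRUE`).
#'
#' @return An object of class `peptide_matrix`: a list with elements
#'   `intensities`, `peptides` and `samples`.
#' @export
#' @examples
#' m <- matrix(c(10, 20, NA, 40), 2, 2,
#'             dimnames = list(NULL, c("s1", "s2")))
#' pep <- data.frame(peptide_sequence = c("AAAK", "CCDR"),
#'                   charge = 2L, protein_id = "P1")
#' peptide_matrix(m, pep)
peptide_matrix <- function(intensities, peptides) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  peptides <- as.data.frame(peptides, stringsAsFactors = FALSE)
  required <- c("peptide_sequence", "charge", "protein_id")
  missing_cols <- setdiff(required, names(peptides))
  if (length(missing_cols) > 0L)
    stop("peptide annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"is_unique" %in% names(peptides)) peptides$is_unique <- TRUE
  if (nrow(peptides) != nrow(intensities))
    stop("peptide annotation has ", nrow(peptides),
         " rows but intensity matrix has ", nrow(intensities))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("sample_", seq_len(ncol(intensities)))
  peptides$peptide_sequence <- as.character(peptides$peptide_sequence)
  peptides$charge <- as.integer(peptides$charge)
  peptides$protein_id <- as.character(peptides$protein_id)
  peptides$is_unique <- as.logical(peptides$is_unique)
  if (any(!nzchar(peptides$peptide_sequence)))
    stop("empty peptide sequence")
  if (any(is.na(peptides$charge) | peptides$charge < 1L))
    stop("precursor charge must be a positive integer")
  key <- paste(peptides$peptide_sequence, peptides$charge, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate precursor (sequence, charge): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- which(!is.na(intensities) & intensities <= 0)
  if (length(bad) > 0L)
    stop("intensities must be strictly positive where present; ",
         "found non-positive value(s). Encode non-detection as NA, not 0.")
  rownames(intensities) <- key
  rownames(peptides) <- key
  structure(list(intensities = intensities,
                 peptides = peptides,
                 samples = colnames(intensities)),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  n_missing <- sum(is.na(x$intensities))
  cat(sprintf(
    "peptide_matrix: %d precursors x %d samples (%d proteins, %.1f%% missing)\n",
    nrow(x$intensities), ncol(x$intensities),
    length(unique(x$peptides$protein_id)),
    100 * n_missing / length(x$intensities)))
  invisible(x)
}

#' @export
dim.peptide_matrix <- function(x) dim(x$intensities)

#' Restrict a peptide matrix to the unique precursors of one protein
#'
#' Shared peptides (`is_unique = FALSE`) are excluded from inference by
#' default; set `include_shared = TRUE` to keep them (they are then treated
#' as evidence for this parent, which is not the default behaviour of any
#' inference method here).
#'
#' @param x a [peptide_matrix()]
#' @param protein_id protein identifier
#' @param include_shared keep shared peptides as well?
#' @return a `peptide_matrix` restricted to the protein's precursors
#' @export
protein_peptides <- function(x, protein_id, include_shared = FALSE) {
  stopifnot(inherits(x, "peptide_matrix"))
  sel <- x$peptides$protein_id == protein_id
  if (!include_shared) sel <- sel & x$peptides$is_unique
  if (!any(x$peptides$protein_id == protein_id))
    stop("unknown protein id: ", protein_id)
  peptide_matrix(x$intensities[sel, , drop = FALSE],
                 x$peptides[sel, , drop = FALSE])
}

#' Protein metadata table
#'
#' @param protein_id character vector of identifiers
#' @param molecular_weight molecular weights in Da (> 0)
#' @param length protein length in residues (optional, `NA` allowed)
#' @param sequence amino-acid sequence (optional)
#' @param theoretical_peptides expected number of fully tryptic peptides
#'   (optional; filled by [count_tryptic_peptides()] when sequences are
#'   available)
#' @return data.frame of class `protein_info`, one row per protein, with
#'   `protein_id` as row names.
#' @export
protein_info <- function(protein_id, molecular_weight, length = NA_integer_,
                         sequence = NA_character_,
                         theoretical_peptides = NA_integer_) {
  protein_id <- as.character(protein_id)
  n <- length(protein_id)
  if (anyDuplicated(protein_id)) stop("duplicate protein ids")
  if (any(is.na(molecular_weight) | molecular_weight <= 0))
    stop("molecular_weight must be > 0")
  info <- data.frame(protein_id = protein_id,
                     molecular_weight = rep_len(as.numeric(molecular_weight),
                                                n),
                     length = rep_len(as.integer(length), n),
                     sequence = rep_len(as.character(sequence), n),
                     theoretical_peptides =
                       rep_len(as.integer(theoretical_peptides), n),
                     stringsAsFactors = FALSE)
  has_seq <- !is.na(info$sequence)
  if (any(has_seq & !is.na(info$length) &
          info$length != nchar(info$sequence)))
    stop("length field disagrees with sequence length")
  info$length[has_seq] <- nchar(info$sequence[has_seq])
  rownames(info) <- info$protein_id
  class(info) <- c("protein_info", "data.frame")
  info
}

#' Absolute reference standard
#'
#' An externally determined set of absolute protein mass fractions (for
#' example, ribosome-profiling-derived synthesis rates converted to mass
#' fractions) used to calibrate relative proteomics data, together with the
#' ids of the calibration samples it refers to.
#'
#' @param protein_id character vector
#' @param rho absolute mass fractions, all >= 0, summing to at most 1 (plus
#'   a small tolerance for round-off in published tables)
#' @param calibration_samples character vector of sample ids the standard
#'   was measured in
#' @return list of class `reference_standard` with elements `rho` (named
#'   numeric) and `calibration_samples`.
#' @export
reference_standard <- function(protein_id, rho, calibration_samples) {
  protein_id <- as.character(protein_id)
  rho <- as.numeric(rho)
  if (length(protein_id) != length(rho))
    stop("protein_id and rho lengths differ")
  if (anyDuplicated(protein_id)) stop("duplicate protein ids in standard")
  if (any(is.na(rho) | rho < 0)) stop("rho must be >= 0")
  if (sum(rho) > 1 + 1e-6)
    stop("reference mass fractions sum to ", format(sum(rho)),
         " > 1; not a valid set of mass fractions")
  names(rho) <- protein_id
  structure(list(rho = rho,
                 calibration_samples = as.character(calibration_samples)),
            class = "reference_standard")
}

#' Sample metadata table
#'
#' @param sample_id character vector
#' @param growth_rate growth rates in 1/h (`NA` allowed, positive otherwise)
#' @param limitation one of `"C"`, `"A"`, `"R"` or `"none"` per sample
#' @param replicate_group grouping label for replicates
#' @return data.frame of class `sample_meta`
#' @export
sample_meta <- function(sample_id, growth_rate = NA_real_,
                        limitation = "none", replicate_group = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids")
  growth_rate <- as.numeric(growth_rate)
  if (any(!is.na(growth_rate) & growth_rate <= 0))
    stop("growth_rate must be positive when present")
  limitation <- as.character(limitation)
  if (!all(limitation %in% c("C", "A", "R", "none")))
    stop("limitation must be one of C, A, R, none")
  meta <- data.frame(sample_id = sample_id,
                     growth_rate = growth_rate,
                     limitation = rep_len(limitation, length(sample_id)),
                     replicate_group = rep_len(as.character(replicate_group),
                                               length(sample_id)),
                     stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  class(meta) <- c("sample_meta", "data.frame")
  meta
}

#' Definition of a protein complex with known stoichiometry
#'
#' @param name complex name
#' @param protein_id member protein ids (at least two)
#' @param copies stoichiometric copies of each member per complex (>= 1)
#' @return list of class `complex_definition`
#' @export
complex_definition <- function(name, protein_id, copies) {
  protein_id <- as.character(protein_id)
  copies <- as.integer(copies)
  if (length(protein_id) < 2L) stop("a complex needs at least 2 members")
  if (length(copies) != length(protein_id))
    stop("copies must match protein_id in length")
  if (any(is.na(copies) | copies < 1L)) stop("copies must be >= 1")
  if (anyDuplicated(protein_id)) stop("duplicate member protein ids")
  structure(list(name = as.character(name),
                 members = data.frame(protein_id = protein_id,
                                      copies = copies,
                                      stringsAsFactors = FALSE)),
            class = "complex_definition")
}
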