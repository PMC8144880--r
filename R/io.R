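#' Read a peptide-precursor intensity matrix from delimited text
#'
#' Two layouts are supported. `"wide"`: one row per precursor, annotation
#' columns followed by one intensity column per sample. `"long"`: columns
#' (peptide_sequence, charge, protein_id, sample, intensity), one row per
#' observed (precursor, sample) pair; precursor/sample pairs absent from
#' the file are missing. In both layouts an empty cell, any code listed in
#' `missing_codes`, and a numeric zero are read as *missing* -- internally
#' missing is a dedicated state (`NA`), never 0.
#'
#' Column names in the file can deviate from the canonical ones; supply
#' `col_map` to map canonical names to the file's header (e.g.
#' `col_map = c(peptide_sequence = "Sequence", charge = "Charge")`).
#'
#' @param path file path
#' @param layout `"wide"` or `"long"`
#' @param missing_codes character codes to treat as missing (in addition to
#'   empty cells and zeros)
#' @param sep field delimiter, tab by default
#' @param col_map named character vector renaming annotation columns
#' @return a [peptide_matrix()]
#' @export
read_peptide_matrix <- function(path, layout = c("wide", "long"),
                                missing_codes = c("", "NA"), sep = "\t",
                                col_map = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      j <- match(col_map[[canon]], names(raw))
      if (is.na(j)) stop("column '", col_map[[canon]],
                         "' (mapped to ", canon, ") not found in header")
      names(raw)[j] <- canon
    }
  }
  anno_cols <- c("peptide_sequence", "charge", "protein_id")
  if (!all(anno_cols %in% names(raw)))
    stop("malformed header: expected columns ",
         paste(setdiff(anno_cols, names(raw)), collapse = ", "),
         " (use col_map= to rename)")
  has_unique <- "is_unique" %in% names(raw)

  parse_intensity <- function(txt, lines) {
    val <- suppressWarnings(as.numeric(txt))
    is_missing <- txt %in% missing_codes | is.na(txt) |
      (!is.na(val) & val == 0)
    bad_numeric <- !is_missing & is.na(val)
    if (any(bad_numeric))
      stop("unparseable intensity '", txt[which(bad_numeric)[1L]],
           "' at line ", lines[which(bad_numeric)[1L]])
    neg <- !is_missing & val < 0
    if (any(neg))
      stop("negative intensity ", val[which(neg)[1L]],
           " at line ", lines[which(neg)[1L]])
    val[is_missing] <- NA_real_
    val
  }

  if (layout == "wide") {
    sample_cols <- setdiff(names(raw),
                           c(anno_cols, "is_unique"))
    if (length(sample_cols) == 0L)
      stop("malformed header: no sample columns found")
    lines <- seq_len(nrow(raw)) + 1L  # header is line 1
    key <- paste(raw$peptide_sequence, raw$charge, sep = "/")
    if (anyDuplicated(key))
      stop("duplicate precursor '", key[which(duplicated(key))[1L]],
           "' at line ", lines[which(duplicated(key))[1L]])
    m <- vapply(sample_cols,
                function(s) parse_intensity(raw[[s]], lines),
                numeric(nrow(raw)))
    m <- matrix(m, nrow = nrow(raw),
                dimnames = list(NULL, sample_cols))
    peptides <- raw[anno_cols]
    peptides$is_unique <- if (has_unique)
      parse_logical(raw$is_unique) else TRUE
    peptide_matrix(m, peptides)
  } else {
    if (!all(c("sample", "intensity") %in% names(raw)))
      stop("malformed header: long layout needs 'sample' and 'intensity'")
    lines <- seq_len(nrow(raw)) + 1L
    val <- parse_intensity(raw$intensity, lines)
    key <- paste(raw$peptide_sequence, raw$charge, sep = "/")
    pair <- paste(key, raw$sample, sep = "@")
    if (anyDuplicated(pair))
      stop("duplicate (precursor, sample) pair at line ",
           lines[which(duplicated(pair))[1L]])
    precursors <- !duplicated(key)
    peptides <- raw[precursors, anno_cols]
    peptides$is_unique <- if (has_unique)
      parse_logical(raw$is_unique[precursors]) else TRUE
    samples <- unique(raw$sample)
    m <- matrix(NA_real_, nrow = nrow(peptides), ncol = length(samples),
                dimnames = list(key[precursors], samples))
    m[cbind(match(key, key[precursors]), match(raw$sample, samples))] <- val
    peptide_matrix(m, peptides)
  }
}

parse_logical <- function(x) {
  tolower(x) %in% c("true", "t", "1", "yes")
}

#' Write a peptide matrix as wide delimited text
#'
#' Annotation columns (`peptide_sequence`, `charge`, `protein_id`,
#' `is_unique`) followed by one intensity column per sample; missing
#' entries become empty fields. [read_peptide_matrix()] reproduces the
#' object exactly.
#'
#' @param x a [peptide_matrix()]
#' @param path output file path
#' @param sep field delimiter
#' @export
write_peptide_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "peptide_matrix"))
  txt <- matrix(sprintf("%.17g", x$intensities),
                nrow = nrow(x$intensities))
  txt[is.na(x$intensities)] <- ""
  df <- cbind(x$peptides[c("peptide_sequence", "charge", "protein_id",
                           "is_unique")],
              as.data.frame(txt, stringsAsFactors = FALSE))
  names(df) <- c("peptide_sequence", "charge", "protein_id", "is_unique",
                 x$samples)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(TRUE)
}

#' Write a protein (or mass-fraction) matrix as wide delimited text
#'
#' Values are written with 17 significant digits so that a read-back with
#' [read_protein_matrix()] reproduces them exactly; missing entries are
#' written as empty fields.
#'
#' @param matrix numeric matrix, proteins x samples, `NA` = missing
#' @param path output file path
#' @param sep field delimiter
#' @export
write_protein_matrix <- function(matrix, path, sep = "\t") {
  stopifnot(is.matrix(matrix))
  if (is.null(rownames(matrix))) stop("matrix must have protein row names")
  txt <- matrix(sprintf("%.17g", matrix), nrow = nrow(matrix))
  txt[is.na(matrix)] <- ""
  df <- data.frame(protein_id = rownames(matrix), txt,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("protein_id", colnames(matrix))
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ",
                              conditionMessage(e)))
  invisible(ok)
}

#' Read a protein matrix written by [write_protein_matrix()]
#'
#' @inheritParams write_protein_matrix
#' @return numeric matrix with protein row names; empty fields become `NA`
#' @export
read_protein_matrix <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1L] != "protein_id")
    stop("malformed header: first column must be protein_id")
  m <- vapply(raw[-1L], function(col) {
    col[col == ""] <- NA_character_
    as.numeric(col)
  }, numeric(nrow(raw)))
  m <- matrix(m, nrow = nrow(raw),
              dimnames = list(raw$protein_id, names(raw)[-1L]))
  m
}

# Standard average (not monoisotopic) residue masses in Da, plus water for
# the termini. Ambiguity codes: B = avg(N, D), Z = avg(Q, E), X = average
# over the 20 standard residues, U = selenocysteine.
AVERAGE_RESIDUE_MASS <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0106

residue_mass_table <- function() {
  base <- AVERAGE_RESIDUE_MASS
  c(base,
    B = unname((base["N"] + base["D"]) / 2),
    Z = unname((base["Q"] + base["E"]) / 2),
    X = unname(mean(base)),
    U = 150.0379)
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water. Ambiguity codes B/Z/X are
#' assigned the average mass of their candidate residues; U is
#' selenocysteine.
#'
#' @param sequence character vector of amino-acid sequences
#' @return numeric vector of molecular weights in Da
#' @export
protein_molecular_weight <- function(sequence) {
  masses <- residue_mass_table()
  vapply(sequence, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_real_)
    aa <- strsplit(toupper(s), "")[[1L]]
    unknown <- setdiff(aa, names(masses))
    if (length(unknown) > 0L)
      stop("sequence contains non-amino-acid character(s): ",
           paste(unknown, collapse = ", "))
    sum(masses[aa]) + WATER_MASS
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Read protein sequences from FASTA
#'
#' Sequences are read with Biostrings; protein ids are extracted from the
#' FASTA headers with `header_regex` (first capture group, or the whole
#' match if the pattern has no group). Molecular weights are computed from
#' average residue masses; if an external molecular-weight table is
#' available it takes precedence (see [protein_info()]).
#'
#' @param path FASTA file
#' @param header_regex regular expression applied to each header line
#' @param min_len,max_len tryptic peptide length window forwarded to
#'   [count_tryptic_peptides()]
#' @param count_peptides also fill the `theoretical_peptides` column?
#' @return a [protein_info()] table (empty, with a warning, for an empty
#'   file)
#' @export
read_protein_fasta <- function(path, header_regex = "^(\\S+)",
                               min_len = 6L, max_len = 30L,
                               count_peptides = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_info(character(0), numeric(0)))
  }
  headers <- names(seqs)
  m <- regexec(header_regex, headers)
  ids <- vapply(seq_along(headers), function(i) {
    hit <- regmatches(headers[i], m[i])[[1L]]
    if (length(hit) == 0L)
      stop("header does not match header_regex: ", headers[i])
    if (length(hit) > 1L) hit[2L] else hit[1L]
  }, character(1L))
  sequence <- toupper(as.character(seqs))
  allowed <- names(residue_mass_table())
  for (i in seq_along(sequence)) {
    bad <- setdiff(strsplit(sequence[i], "")[[1L]], allowed)
    if (length(bad) > 0L)
      stop("record '", ids[i], "' contains non-amino-acid character(s): ",
           paste(bad, collapse = ", "))
  }
  info <- protein_info(
    protein_id = ids,
    molecular_weight = protein_molecular_weight(sequence),
    sequence = sequence,
    theoretical_peptides = if (count_peptides)
      vapply(sequence, count_tryptic_peptides, integer(1L),
             min_len = min_len, max_len = max_len, USE.NAMES = FALSE)
    else NA_integer_)
  info
}

#' Read an absolute reference standard from two-column delimited text
#'
#' @param path file with columns `protein_id` and `rho`
#' @param calibration_samples sample ids the standard refers to
#' @param sep field delimiter
#' @return a [reference_standard()]
#' @export
read_reference_standard <- function(path, calibration_samples, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("protein_id", "rho") %in% names(raw)))
    stop("malformed header: expected columns protein_id, rho")
  reference_standard(raw$protein_id, raw$rho, calibration_samples)
}

#' Read complex definitions from delimited text
#'
#' @param path file with columns `complex`, `protein_id`, `copies`
#' @param sep field delimiter
#' @return named list of [complex_definition()] objects
#' @export
read_complex_definitions <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("complex", "protein_id", "copies") %in% names(raw)))
    stop("malformed header: expected columns complex, protein_id, copies")
  out <- lapply(split(raw, raw$complex), function(d)
    complex_definition(d$complex[1L], d$protein_id, d$copies))
  out
}

#' Read sample metadata from delimited text
#'
#' @param path file with columns `sample_id` and optionally `growth_rate`,
#'   `limitation`, `replicate_group`, `is_reference`
#' @param sep field delimiter
#' @return a [sample_meta()] table (with an `is_reference` column when the
#'   file provides one)
#' @export
read_sample_meta <- function(path, sep = "\t") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(raw))
    stop("malformed header: expected column sample_id")
  meta <- sample_meta(
    raw$sample_id,
    growth_rate = if ("growth_rate" %in% names(raw))
      raw$growth_rate else NA_real_,
    limitation = if ("limitation" %in% names(raw))
      raw$limitation else "none",
    replicate_group = if ("replicate_group" %in% names(raw))
      raw$replicate_group else NA_character_)
  if ("is_reference" %in% names(raw))
    meta$is_reference <- parse_logical(as.character(raw$is_reference))
  meta
}
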