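#' Rank the precursors of a protein by average intensity
#'
#' Precursors are ranked by their mean intensity across all samples with
#' missing values set to 0 *inside the ranking only* (missingness is never
#' conflated with zero elsewhere). Ties are broken lexicographically by
#' (peptide sequence, charge) for reproducibility.
#'
#' @param x a [peptide_matrix()]
#' @param protein_id protein to rank
#' @param include_shared forward to [protein_peptides()]
#' @return the protein's precursor annotation rows, in descending rank
#'   order, with a `mean_intensity` column appended
#' @export
rank_peptides <- function(x, protein_id, include_shared = FALSE) {
  sub <- protein_peptides(x, protein_id, include_shared = include_shared)
  m <- sub$intensities
  m[is.na(m)] <- 0
  means <- rowMeans(m)
  ord <- order(-means, sub$peptides$peptide_sequence, sub$peptides$charge)
  out <- sub$peptides[ord, , drop = FALSE]
  out$mean_intensity <- means[ord]
  out
}

#' TopPepN protein inference
#'
#' For each protein, the N most intense precursors (ranked once, globally,
#' by across-sample average intensity) are selected and their intensities
#' summed per sample, counting only entries actually present in that
#' sample. A protein is undetected in a sample when none of its top-N
#' precursors is present there; in particular TopPep1 yields no value in
#' samples where the single top peptide was not detected.
#'
#' @param x a [peptide_matrix()]
#' @param N number of top precursors to sum (N >= 1); `N = 1` is TopPep1,
#'   `N = 3` TopPep3
#' @param include_shared include shared peptides (non-default behaviour)
#' @return proteins x samples intensity matrix (`NA` = undetected) with
#'   attribute `method` set to `"toppep1"`, `"toppep3"`, or `"toppepN"`
#' @export
toppep <- function(x, N = 1L, include_shared = FALSE) {
  stopifnot(inherits(x, "peptide_matrix"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be >= 1")
  proteins <- inference_proteins(x, include_shared)
  out <- matrix(NA_real_, length(proteins), ncol(x$intensities),
                dimnames = list(proteins, x$samples))
  for (pid in proteins) {
    ranked <- rank_peptides(x, pid, include_shared = include_shared)
    keys <- rownames(ranked)[seq_len(min(N, nrow(ranked)))]
    sub <- x$intensities[keys, , drop = FALSE]
    n_present <- colSums(!is.na(sub))
    val <- colSums(sub, na.rm = TRUE)
    val[n_present == 0L] <- NA_real_
    out[pid, ] <- val
  }
  structure(out, method = if (N == 1L) "toppep1"
            else if (N == 3L) "toppep3" else "toppepN")
}

#' Count fully tryptic peptides of a protein sequence
#'
#' Trypsin cleaves C-terminal to K or R, except when the next residue is
#' proline. With zero missed cleavages the sequence decomposes into a
#' unique set of fragments; the count returned is the number of fragments
#' whose length falls in `[min_len, max_len]` (defaults 6-30, the usual
#' detectable window for bottom-up proteomics). This is the denominator of
#' the iBAQ estimator.
#'
#' @param sequence amino-acid string
#' @param min_len,max_len inclusive peptide length window
#' @return integer count
#' @export
#' @examples
#' count_tryptic_peptides("AAAAAKGGGGGGR")  # 2 fragments, both in window
#' count_tryptic_peptides("AAAAAKPGGGGGR")  # KP: no cleavage -> 1
count_tryptic_peptides <- function(sequence, min_len = 6L, max_len = 30L) {
  if (is.na(sequence) || !nzchar(sequence)) stop("empty sequence")
  frags <- digest_tryptic(sequence)
  len <- nchar(frags)
  sum(len >= min_len & len <= max_len)
}

# Fully tryptic fragments (zero missed cleavages, no cleavage before P).
digest_tryptic <- function(sequence) {
  cuts <- gregexpr("(?<=[KR])(?!P)", sequence, perl = TRUE)[[1L]]
  cuts <- cuts[cuts > 0L & cuts <= nchar(sequence)]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, nchar(sequence))
  substring(sequence, starts, ends)
}

#' iBAQ protein inference
#'
#' Per sample, the intensities of all present precursors of a protein are
#' summed and divided by the protein's expected number of fully tryptic
#' peptides (see [count_tryptic_peptides()]). Proteins without a positive
#' theoretical peptide count are skipped with a warning.
#'
#' @param x a [peptide_matrix()]
#' @param info a [protein_info()] table with `theoretical_peptides` filled
#' @param include_shared include shared peptides (non-default behaviour)
#' @return proteins x samples intensity matrix with attribute
#'   `method = "ibaq"`
#' @export
ibaq <- function(x, info, include_shared = FALSE) {
  stopifnot(inherits(x, "peptide_matrix"))
  proteins <- inference_proteins(x, include_shared)
  counts <- info$theoretical_peptides[match(proteins, info$protein_id)]
  usable <- !is.na(counts) & counts > 0L
  if (any(!usable))
    warning("skipping ", sum(!usable),
            " protein(s) without a theoretical tryptic-peptide count: ",
            paste(utils::head(proteins[!usable], 5L), collapse = ", "),
            if (sum(!usable) > 5L) ", ..." else "")
  proteins <- proteins[usable]
  counts <- counts[usable]
  out <- matrix(NA_real_, length(proteins), ncol(x$intensities),
                dimnames = list(proteins, x$samples))
  for (i in seq_along(proteins)) {
    sub <- protein_peptides(x, proteins[i], include_shared = include_shared)
    m <- sub$intensities
    n_present <- colSums(!is.na(m))
    val <- colSums(m, na.rm = TRUE) / counts[i]
    val[n_present == 0L] <- NA_real_
    out[i, ] <- val
  }
  structure(out, method = "ibaq")
}

# Proteins eligible for inference: those with at least one usable precursor
# present in at least one sample.
inference_proteins <- function(x, include_shared = FALSE) {
  pep <- x$peptides
  keep <- if (include_shared) rep(TRUE, nrow(pep)) else pep$is_unique
  present <- rowSums(!is.na(x$intensities)) > 0L
  sort(unique(pep$protein_id[keep & present]))
}
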