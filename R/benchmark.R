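#' Per-protein coefficient of variation across samples
#'
#' CV = sample SD (n-1 denominator) / mean, reported in percent. Only
#' proteins detected in every selected sample are included, so all methods
#' can be compared on the same protein set.
#'
#' @param intensities proteins x samples matrix
#' @param samples columns to use (default: all); at least 2
#' @param proteins optionally restrict to these proteins (e.g. the common
#'   detected set across several methods)
#' @return list with `cv` (named per-protein CV in %, complete cases only)
#'   and `median_cv`
#' @export
protein_cv <- function(intensities, samples = colnames(intensities),
                       proteins = NULL) {
  m <- intensities[, samples, drop = FALSE]
  if (ncol(m) < 2L) stop("need at least 2 samples")
  if (!is.null(proteins)) m <- m[rownames(m) %in% proteins, , drop = FALSE]
  complete <- rowSums(is.na(m)) == 0L
  if (!any(complete))
    stop("no protein detected in all selected samples")
  m <- m[complete, , drop = FALSE]
  cv <- 100 * apply(m, 1L, stats::sd) / rowMeans(m)
  list(cv = cv, median_cv = stats::median(cv), n = nrow(m))
}

#' Variance of log-ratios between two replicate samples
#'
#' Over the proteins quantified in both samples, computes
#' `var(log2(I_A / I_B))` (n-1 denominator). Adding a common factor to one
#' sample shifts the mean log-ratio but leaves this variance unchanged.
#'
#' @param intensities proteins x samples matrix
#' @param sample_a,sample_b column names of the two replicates
#' @return list with `variance`, `log2_ratios`, and `n`
#' @export
replicate_logratio_variance <- function(intensities, sample_a, sample_b) {
  a <- intensities[, sample_a]
  b <- intensities[, sample_b]
  both <- !is.na(a) & !is.na(b)
  if (!any(both)) stop("no protein quantified in both samples")
  lr <- log2(a[both] / b[both])
  list(variance = stats::var(lr), log2_ratios = lr, n = sum(both))
}

#' Concordance of fold changes between proteomics and a standard
#'
#' For proteins quantified in all four vectors, compares the proteomics
#' fold change `phi_cond / phi_ref` with the standard's `rho_cond /
#' rho_ref`. A protein is discrepant when the two fold changes differ by
#' more than `threshold`-fold in either direction.
#'
#' @param phi_cond,phi_ref named proteomics mass-fraction vectors for the
#'   perturbed and reference conditions
#' @param rho_cond,rho_ref named standard mass-fraction vectors
#' @param threshold fold-difference defining a discrepancy (default 2)
#' @return list with `pearson_r` (of the two log2 fold-change vectors),
#'   `fraction_discrepant`, and `n`
#' @export
foldchange_concordance <- function(phi_cond, phi_ref, rho_cond, rho_ref,
                                   threshold = 2) {
  ids <- Reduce(intersect, list(names(phi_cond), names(phi_ref),
                                names(rho_cond), names(rho_ref)))
  keep <- ids[!is.na(phi_cond[ids]) & !is.na(phi_ref[ids]) &
                !is.na(rho_cond[ids]) & !is.na(rho_ref[ids])]
  if (length(keep) == 0L) stop("no protein quantified in all four vectors")
  fc_phi <- log2(phi_cond[keep] / phi_ref[keep])
  fc_rho <- log2(rho_cond[keep] / rho_ref[keep])
  disc <- abs(fc_phi - fc_rho) > log2(threshold)
  list(pearson_r = stats::cor(fc_phi, fc_rho),
       fraction_discrepant = mean(disc),
       n = length(keep))
}

#' Multilinear regression of quantification bias
#'
#' Regresses the log2 ratio of proteomics to standard mass fractions on
#' protein size (log2 molecular weight) and indicators for proteins
#' detected with only one or only two peptide precursors. The variance
#' explained by each factor is attributed sequentially (type-I sums of
#' squares) in that fixed order; pass `order` to change it.
#'
#' @param phi named proteomics mass fractions
#' @param rho named standard mass fractions
#' @param info a [protein_info()] table (molecular weights)
#' @param peptide_counts named integer vector: detected precursors per
#'   protein
#' @param order covariate order for the sequential attribution
#' @return list of class `bias_regression` with `coefficients`,
#'   `total_variance`, `explained_share` (per factor, fractions of the
#'   total variance), `r_squared`, and `n`
#' @export
bias_regression <- function(phi, rho, info, peptide_counts,
                            order = c("log2_mw", "one_peptide",
                                      "two_peptides")) {
  ids <- intersect(names(phi), names(rho))
  ids <- ids[!is.na(phi[ids]) & !is.na(rho[ids]) & phi[ids] > 0 &
               rho[ids] > 0]
  if (length(ids) < 5L) stop("too few proteins shared between phi and rho")
  mw <- info$molecular_weight[match(ids, info$protein_id)]
  npep <- peptide_counts[ids]
  d <- data.frame(y = log2(phi[ids] / rho[ids]),
                  log2_mw = log2(mw),
                  one_peptide = as.numeric(npep == 1L),
                  two_peptides = as.numeric(npep == 2L))
  order <- match.arg(order, c("log2_mw", "one_peptide", "two_peptides"),
                     several.ok = TRUE)
  collapsed <- vapply(d[order], function(col) stats::var(col) == 0,
                      logical(1L))
  if (any(collapsed))
    stop("rank-deficient design: covariate(s) constant: ",
         paste(order[collapsed], collapse = ", "))
  fml <- stats::reformulate(order, response = "y")
  fit <- stats::lm(fml, data = d)
  an <- stats::anova(fit)
  total_ss <- sum(an[["Sum Sq"]])
  shares <- if (total_ss > 0) an[order, "Sum Sq"] / total_ss
            else rep(0, length(order))
  names(shares) <- order
  structure(list(coefficients = stats::coef(fit),
                 total_variance = stats::var(d$y),
                 explained_share = shares,
                 r_squared = sum(shares),
                 n = length(ids)),
            class = "bias_regression")
}

#' Total-variation distance between two proteome compositions
#'
#' `0.5 * sum_i |phi_A_i - phi_B_i|` over the union of proteins; a protein
#' missing from one proteome contributes its full mass fraction from the
#' other. Ranges from 0 (identical compositions) to 1 (disjoint), and is a
#' metric on normalized compositions.
#'
#' @param phi_a,phi_b named mass-fraction vectors, each summing to 1 over
#'   its non-missing entries
#' @param tol allowed deviation of each input's sum from 1
#' @return distance in `[0, 1]`
#' @export
proteome_distance <- function(phi_a, phi_b, tol = 1e-6) {
  for (v in list(phi_a, phi_b)) {
    s <- sum(v, na.rm = TRUE)
    if (abs(s - 1) > tol)
      stop("unnormalized input: mass fractions sum to ", format(s))
  }
  ids <- union(names(phi_a), names(phi_b))
  a <- ifelse(is.na(phi_a[ids]), 0, phi_a[ids])
  b <- ifelse(is.na(phi_b[ids]), 0, phi_b[ids])
  a[is.na(a)] <- 0  # ids absent from a vector index as NA
  b[is.na(b)] <- 0
  0.5 * sum(abs(a - b))
}

#' Number of detected precursors per protein
#'
#' @param x a [peptide_matrix()]
#' @param include_shared include shared peptides
#' @return named integer vector: precursors with at least one present
#'   intensity, per protein
#' @export
detected_precursor_counts <- function(x, include_shared = FALSE) {
  pep <- x$peptides
  keep <- (include_shared | pep$is_unique) &
    rowSums(!is.na(x$intensities)) > 0L
  counts <- table(pep$protein_id[keep])
  stats::setNames(as.integer(counts), names(counts))
}

#' Mean number of proteins detected per sample
#'
#' @param intensities proteins x samples matrix
#' @return average count of non-missing proteins per sample
#' @export
mean_detected_proteins <- function(intensities) {
  mean(colSums(!is.na(intensities)))
}
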