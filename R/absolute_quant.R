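#' Convert protein intensities to proteome mass fractions
#'
#' Since intensity-based inference most naturally reflects protein copy
#' numbers, each intensity is multiplied by the protein's molecular weight
#' and the resulting masses are normalized to sum to 1 within each sample
#' (over the proteins detected in that sample).
#'
#' @param intensities proteins x samples matrix (`NA` = undetected)
#' @param info a [protein_info()] table covering every detected protein
#' @return proteins x samples matrix of mass fractions; every column sums
#'   to 1 over its non-missing entries
#' @export
to_mass_fractions <- function(intensities, info) {
  stopifnot(is.matrix(intensities))
  mw <- info$molecular_weight[match(rownames(intensities),
                                    info$protein_id)]
  if (anyNA(mw[rowSums(!is.na(intensities)) > 0L]))
    stop("molecular weight unknown for detected protein(s): ",
         paste(utils::head(rownames(intensities)[is.na(mw)], 5L),
               collapse = ", "))
  mass <- intensities * mw
  totals <- colSums(mass, na.rm = TRUE)
  if (any(totals <= 0))
    stop("sample(s) with zero total protein mass: ",
         paste(colnames(intensities)[totals <= 0], collapse = ", "))
  sweep(mass, 2L, totals, "/")
}

#' Check that each column of a mass-fraction matrix sums to 1
#' @param fractions proteins x samples mass-fraction matrix
#' @param tol allowed deviation of each column sum from 1
#' @return `fractions`, invisibly; error when a column is off
#' @export
validate_mass_fractions <- function(fractions, tol = 1e-6) {
  sums <- colSums(fractions, na.rm = TRUE)
  off <- abs(sums - 1) > tol
  if (any(off))
    stop("mass-fraction column(s) do not sum to 1: ",
         paste(sprintf("%s (%.8f)", colnames(fractions)[off], sums[off]),
               collapse = ", "))
  if (any(fractions < 0, na.rm = TRUE)) stop("negative mass fraction")
  invisible(fractions)
}

#' Calibrate relative mass fractions against an absolute standard
#'
#' Each protein receives a condition-independent scaling factor
#' `c_i = rho_i / geomean(phi_i over the calibration samples)`, computed
#' from the calibration samples in which the protein was detected; the
#' geometric mean across calibration replicates matches the multiplicative
#' error model of intensity data. Proteins absent from every calibration
#' sample, or absent from the standard, keep a factor of 1. The rescaled
#' values are re-normalized to sum to 1 per sample (mass fractions of total
#' detected protein); set `renormalize = FALSE` to preserve the standard's
#' absolute scale instead.
#'
#' @param fractions proteins x samples mass-fraction matrix
#' @param std a [reference_standard()]; its `calibration_samples` must be
#'   columns of `fractions`
#' @param renormalize re-normalize columns to sum to 1 after rescaling
#' @return calibrated mass-fraction matrix with attribute
#'   `scaling_factors` (named vector of the `c_i`)
#'
#' @details Calibration is exactly idempotent without renormalization,
#'   and with renormalization whenever the standard covers every protein
#'   detected in the calibration samples (the usual case; the residual
#'   rescaling is then uniform). With partial coverage plus
#'   renormalization, repeated application shifts factor-1 proteins
#'   relative to covered ones by the covered mass deficit.
#' @export
calibrate_to_standard <- function(fractions, std, renormalize = TRUE) {
  stopifnot(is.matrix(fractions), inherits(std, "reference_standard"))
  cal <- std$calibration_samples
  missing_samples <- setdiff(cal, colnames(fractions))
  if (length(missing_samples) > 0L)
    stop("calibration sample(s) not in matrix: ",
         paste(missing_samples, collapse = ", "))
  overlap <- intersect(rownames(fractions), names(std$rho))
  if (length(overlap) == 0L)
    stop("no protein shared between matrix and reference standard")
  cal_m <- fractions[, cal, drop = FALSE]
  geo <- apply(cal_m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else exp(mean(log(v)))
  })
  factors <- rep(1, nrow(fractions))
  names(factors) <- rownames(fractions)
  use <- names(geo) %in% overlap & !is.na(geo) & geo > 0
  factors[use] <- std$rho[names(geo)[use]] / geo[use]
  out <- fractions * factors
  if (renormalize) {
    totals <- colSums(out, na.rm = TRUE)
    if (any(totals <= 0)) stop("calibration zeroed out a sample")
    out <- sweep(out, 2L, totals, "/")
  }
  structure(out, scaling_factors = factors)
}

#' Parameters for mass-fraction to concentration conversion
#'
#' @param total_protein_concentration total cellular protein concentration
#'   in proteins per cubic micrometre (default 3e6)
#' @param mean_protein_length abundance-weighted mean protein length in
#'   residues; see [mean_protein_length()] for the self-consistent estimate
#'   from a mass-fraction column
#' @return list of class `concentration_params`
#' @export
concentration_params <- function(total_protein_concentration = 3e6,
                                 mean_protein_length = NULL) {
  if (total_protein_concentration <= 0)
    stop("total_protein_concentration must be > 0")
  if (!is.null(mean_protein_length) && mean_protein_length <= 0)
    stop("mean_protein_length must be > 0")
  structure(list(total_protein_concentration = total_protein_concentration,
                 mean_protein_length = mean_protein_length),
            class = "concentration_params")
}

#' Abundance-weighted mean protein length of a sample
#'
#' Number-weighted mean residue count implied by a mass-fraction vector:
#' `sum(phi) / sum(phi / L)`. With this mean, per-protein number
#' concentrations computed by [number_concentration()] add up exactly to
#' the total protein concentration.
#'
#' @param phi mass fractions (missing entries ignored)
#' @param length protein lengths in residues, parallel to `phi`
#' @return mean length in residues
#' @export
mean_protein_length <- function(phi, length) {
  keep <- !is.na(phi) & !is.na(length)
  if (!any(keep)) stop("no protein with both mass fraction and length")
  sum(phi[keep]) / sum(phi[keep] / length[keep])
}

#' Convert a protein mass fraction to a number concentration
#'
#' `concentration = phi * (mean_protein_length / protein_length) *
#' total_protein_concentration`, in proteins per cubic micrometre. Linear
#' in the mass fraction and inversely proportional to protein length: at
#' the defaults, a mass fraction of 1e-5 for an average-sized protein is
#' 30 proteins/um^3.
#'
#' @param mass_fraction protein mass fraction(s), in `[0, 1]`
#' @param protein_length protein length(s) in residues
#' @param params a [concentration_params()] with `mean_protein_length` set
#' @return concentration(s) in proteins/um^3
#' @export
number_concentration <- function(mass_fraction, protein_length, params) {
  stopifnot(inherits(params, "concentration_params"))
  if (is.null(params$mean_protein_length))
    stop("params$mean_protein_length must be set (see mean_protein_length)")
  if (any(protein_length <= 0, na.rm = TRUE))
    stop("protein_length must be > 0")
  mass_fraction * (params$mean_protein_length / protein_length) *
    params$total_protein_concentration
}

#' Complex concentration estimates from member mass fractions
#'
#' For each detected member of a complex, the member's number
#' concentration is divided by its stoichiometric copy number, yielding an
#' independent estimate of the complex concentration. If members really
#' are produced in stoichiometric amounts, the spread of these estimates
#' reflects the quantification error; the spread is summarized as the
#' log10 ratio of the 95th to the 5th percentile.
#'
#' @param fractions mass-fraction matrix
#' @param sample sample (column) to evaluate
#' @param cdef a [complex_definition()]
#' @param info a [protein_info()] table (residue lengths used when
#'   available, MW/110 Da otherwise)
#' @param params a [concentration_params()]
#' @return list with `estimates` (named, per detected member), `median`,
#'   and `log10_interdecile_spread`; empty estimates with a warning when no
#'   member is detected
#' @export
complex_concentration <- function(fractions, sample, cdef, info, params) {
  stopifnot(inherits(cdef, "complex_definition"))
  members <- cdef$members
  phi <- fractions[match(members$protein_id, rownames(fractions)), sample]
  idx <- match(members$protein_id, info$protein_id)
  len <- info$length[idx]
  len[is.na(len)] <- info$molecular_weight[idx][is.na(len)] / 110
  detected <- !is.na(phi)
  if (!any(detected)) {
    warning("no member of complex '", cdef$name, "' detected in ", sample)
    return(list(estimates = numeric(0), median = NA_real_,
                log10_interdecile_spread = NA_real_))
  }
  est <- number_concentration(phi[detected], len[detected], params) /
    members$copies[detected]
  names(est) <- members$protein_id[detected]
  q <- stats::quantile(est, c(0.05, 0.95), names = FALSE)
  list(estimates = est,
       median = stats::median(est),
       log10_interdecile_spread = log10(q[2L] / q[1L]))
}

#' Surface density of a membrane protein
#'
#' Converts a volumetric number concentration to an areal density by
#' dividing by the cell's surface-to-volume ratio.
#'
#' @param concentration proteins/um^3
#' @param surface_to_volume surface-to-volume ratio in 1/um (> 0)
#' @return density in proteins/um^2
#' @export
surface_density <- function(concentration, surface_to_volume) {
  if (any(surface_to_volume <= 0)) stop("surface_to_volume must be > 0")
  concentration / surface_to_volume
}

#' Fraction of membrane area occupied by a protein
#'
#' Areal density times the circular footprint `pi * (d/2)^2`.
#'
#' @param density proteins/um^2
#' @param footprint_diameter protein footprint diameter in um (e.g.
#'   2.6e-3 um for a porin monomer)
#' @return dimensionless occupied-area fraction
#' @export
occupied_area_fraction <- function(density, footprint_diameter) {
  if (any(footprint_diameter <= 0)) stop("footprint diameter must be > 0")
  density * pi * (footprint_diameter / 2)^2
}
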