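#' Configuration for the peptide-matrix simulator
#'
#' The generator emulates the statistical structure of a DIA/SWATH
#' peptide-precursor matrix: a right-skewed peptides-per-protein
#' distribution (`1 + Poisson(peptide_mean)`), protein abundances spanning
#' several decades, peptide detection efficiencies spread over about a
#' decade (log2 SD 1.5), multiplicative log-normal measurement noise, and
#' missing-not-at-random dropout in which low-intensity entries are lost
#' preferentially (logistic detection probability in log2 intensity), plus
#' a small uniform dropout component. At the defaults roughly 10-20% of
#' entries are missing, concentrated among low-abundant proteins.
#'
#' @param n_proteins number of proteins (default 2000)
#' @param n_samples number of samples (default 7, a replicate design)
#' @param peptide_mean mean of the Poisson part of peptides-per-protein
#' @param abundance_decades span of protein abundances in log10 decades
#' @param base_log2_intensity log2 intensity of the least abundant protein
#' @param efficiency_log2_sd SD of log2 detection efficiencies
#' @param noise_log2_sd measurement noise SD in log2 units
#' @param sample_log2_sd SD of true between-sample intensity variation
#'   (0 = technical replicates)
#' @param dropout_location,dropout_scale logistic detection curve: an
#'   entry of log2 intensity `y` is detected with probability
#'   `plogis((y - dropout_location) / dropout_scale)`
#' @param uniform_dropout additional intensity-independent dropout rate
#' @param seed integer seed; the generator is fully deterministic given it
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_proteins = 2000L, n_samples = 7L,
                       peptide_mean = 7, abundance_decades = 5,
                       base_log2_intensity = 10,
                       efficiency_log2_sd = 1.5, noise_log2_sd = 0.2,
                       sample_log2_sd = 0,
                       dropout_location = 10, dropout_scale = 1.5,
                       uniform_dropout = 0.02, seed = 1L) {
  if (n_proteins < 1L || n_samples < 1L) stop("counts must be positive")
  if (peptide_mean < 0 || abundance_decades <= 0)
    stop("peptide_mean and abundance_decades must be positive")
  if (uniform_dropout < 0 || uniform_dropout > 1)
    stop("uniform_dropout must be in [0, 1]")
  if (noise_log2_sd < 0 || efficiency_log2_sd < 0 || sample_log2_sd < 0)
    stop("SDs must be non-negative")
  if (dropout_scale <= 0) stop("dropout_scale must be > 0")
  structure(list(n_proteins = as.integer(n_proteins),
                 n_samples = as.integer(n_samples),
                 peptide_mean = peptide_mean,
                 abundance_decades = abundance_decades,
                 base_log2_intensity = base_log2_intensity,
                 efficiency_log2_sd = efficiency_log2_sd,
                 noise_log2_sd = noise_log2_sd,
                 sample_log2_sd = sample_log2_sd,
                 dropout_location = dropout_location,
                 dropout_scale = dropout_scale,
                 uniform_dropout = uniform_dropout,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic unique peptide sequence for a global precursor index:
# base-18 encoding over an alphabet without K/R, then a tryptic C-terminal K.
PEPTIDE_ALPHABET <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1L]]
int_to_peptide <- function(n) {
  vapply(n, function(k) {
    digits <- integer(7L)
    for (j in 7:1) { digits[j] <- k %% 18L; k <- k %/% 18L }
    paste0(paste(PEPTIDE_ALPHABET[digits + 1L], collapse = ""), "K")
  }, character(1L))
}

#' Simulate a peptide-precursor matrix with known ground truth
#'
#' Each present intensity is `I_ps = truth_s * eps_p * 2^N(0, sigma)`;
#' entries are then removed by the MNAR detection rule and by uniform
#' dropout. Proteins are generated on independent seeded substreams, so
#' the output is deterministic given the seed and independent of
#' generation order. If dropout removes every observation of a protein,
#' that protein's noise and dropout draws are redrawn (bounded retries).
#'
#' @param config a [sim_config()]
#' @return list with `matrix` (a [peptide_matrix()]), `truth` (proteins x
#'   samples true intensities), `truth_mass_fractions` (the corresponding
#'   mass fractions), `efficiency` (per protein, named vector of true
#'   detection efficiencies, max 1), `info` (a [protein_info()] with
#'   `theoretical_peptides` set to the simulated library size), and
#'   `detected` (the missingness mask)
#' @export
simulate_peptide_matrix <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_proteins
  ns <- config$n_samples
  samples <- sprintf("S%02d", seq_len(ns))
  protein_ids <- sprintf("P%04d", seq_len(n))

  truth <- matrix(NA_real_, n, ns, dimnames = list(protein_ids, samples))
  eff <- vector("list", n)
  pep_rows <- vector("list", n)
  int_rows <- vector("list", n)
  lengths <- integer(n)
  offset <- 0L

  for (i in seq_len(n)) {
    set.seed(config$seed + i * 97L)
    n_pep <- 1L + stats::rpois(1L, config$peptide_mean)
    lengths[i] <- sample(100:600, 1L)
    x0 <- config$base_log2_intensity +
      stats::runif(1L, 0, config$abundance_decades) * log2(10)
    xs <- x0 + stats::rnorm(ns, 0, config$sample_log2_sd)
    e <- stats::rnorm(n_pep, 0, config$efficiency_log2_sd)
    e <- e - max(e)
    ok <- FALSE
    for (try in seq_len(100L)) {
      noise <- matrix(stats::rnorm(n_pep * ns, 0, config$noise_log2_sd),
                      n_pep, ns)
      y <- outer(e, xs, "+") + noise
      p_detect <- stats::plogis((y - config$dropout_location) /
                                  config$dropout_scale) *
        (1 - config$uniform_dropout)
      detected <- matrix(stats::runif(n_pep * ns) < p_detect, n_pep, ns)
      if (any(detected)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("empty matrix: dropout removed all observations of ",
           protein_ids[i], " after bounded retries; ",
           "check dropout_location against the intensity scale")
    m <- 2^y
    m[!detected] <- NA_real_
    truth[i, ] <- 2^xs
    eff[[i]] <- stats::setNames(2^e, int_to_peptide(offset + seq_len(n_pep)))
    int_rows[[i]] <- m
    pep_rows[[i]] <- data.frame(
      peptide_sequence = int_to_peptide(offset + seq_len(n_pep)),
      charge = 2L, protein_id = protein_ids[i], is_unique = TRUE,
      stringsAsFactors = FALSE)
    offset <- offset + n_pep
  }

  intensities <- do.call(rbind, int_rows)
  colnames(intensities) <- samples
  peptides <- do.call(rbind, pep_rows)
  names(eff) <- protein_ids
  info <- protein_info(
    protein_ids,
    molecular_weight = lengths * 110,
    length = lengths,
    theoretical_peptides = vapply(pep_rows, nrow, integer(1L)))
  truth_mass <- truth * info$molecular_weight
  truth_frac <- sweep(truth_mass, 2L, colSums(truth_mass), "/")
  list(matrix = peptide_matrix(intensities, peptides),
       truth = truth,
       truth_mass_fractions = truth_frac,
       efficiency = eff,
       info = info,
       detected = !is.na(intensities))
}

#' Simulate an absolute reference standard from ground truth
#'
#' The standard's mass fractions are the true mass fractions averaged
#' (geometric mean) over the calibration samples, optionally perturbed by
#' log-normal error and restricted to a random subset of proteins.
#'
#' @param truth_mass_fractions proteins x samples true mass fractions (from
#'   [simulate_peptide_matrix()])
#' @param calibration_samples columns defining the standard
#' @param perturb_log2_sd SD (log2 units) of multiplicative error on the
#'   standard; 0 = exact
#' @param coverage fraction of proteins covered by the standard
#' @param seed integer seed
#' @return a [reference_standard()]
#' @export
simulate_reference_standard <- function(truth_mass_fractions,
                                        calibration_samples,
                                        perturb_log2_sd = 0, coverage = 1,
                                        seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1)
  set.seed(seed)
  cal <- truth_mass_fractions[, calibration_samples, drop = FALSE]
  rho <- apply(cal, 1L, function(v) exp(mean(log(v))))
  if (coverage < 1) {
    keep <- sort(sample(length(rho), ceiling(coverage * length(rho))))
    rho <- rho[keep]
  }
  if (perturb_log2_sd > 0) {
    total <- sum(rho)
    rho <- rho * 2^stats::rnorm(length(rho), 0, perturb_log2_sd)
    rho <- rho * total / sum(rho)  # keep a valid mass-fraction total
  }
  reference_standard(names(rho), rho, calibration_samples)
}

# Growth-rate grids of the three limitation series (1/h).
default_lambda_grids <- function() {
  list(C = seq(0.33, 0.91, length.out = 15L),
       A = seq(0.22, 0.84, length.out = 7L),
       R = seq(0.36, 0.98, length.out = 7L))
}

#' Simulate three growth-limitation series with planted sectors
#'
#' Each protein's relative abundance follows `r(lambda) = 1 + s *
#' (lambda - lambda_ref)` within each series, so that `r = 1` in the
#' reference condition; the slope signs are set by the planted sector
#' (upregulated = negative slope) and the magnitudes drawn from
#' `slope_range`. Relative abundances receive multiplicative log-normal
#' noise and are converted to mass fractions by renormalization against
#' log-uniform base abundances.
#'
#' @param n_proteins number of proteins
#' @param plan character vector (recycled) of planted sector labels from
#'   `C, A, R, S, U, C', A', S'`; default cycles through all eight
#' @param slope_range range of |slope| per unit growth rate
#' @param noise_sd SD of the multiplicative noise (natural-log scale,
#'   i.e. ~fractional error; default 5%)
#' @param lambda_grids named list of growth-rate grids for C, A, R
#' @param lambda_ref reference growth rate (1/h)
#' @param seed integer seed
#' @return list with `series` (per limitation: `fractions` including the
#'   shared reference column `REF`, `samples`, `lambda`), `planted`
#'   (protein -> sector), and `reference_sample`
#' @export
simulate_limitation_series <- function(n_proteins = 500L, plan = NULL,
                                       slope_range = c(0.3, 1),
                                       noise_sd = 0.05,
                                       lambda_grids = default_lambda_grids(),
                                       lambda_ref = 0.98, seed = 1L) {
  sectors <- unname(SECTOR_MAP)
  if (is.null(plan)) plan <- rep_len(sectors, n_proteins)
  plan <- rep_len(as.character(plan), n_proteins)
  if (!all(plan %in% sectors))
    stop("plan contains unknown sector label(s): ",
         paste(setdiff(plan, sectors), collapse = ", "))
  if (any(slope_range < 0) || diff(slope_range) < 0)
    stop("slope_range must be non-negative and increasing")
  set.seed(seed)
  protein_ids <- sprintf("P%04d", seq_len(n_proteins))
  names(plan) <- protein_ids
  # sign triple per sector: up (rises as growth slows) = negative slope
  triples <- strsplit(names(SECTOR_MAP)[match(plan, SECTOR_MAP)], ".",
                      fixed = TRUE)
  base <- 10^stats::runif(n_proteins, -5, -1)
  base <- base / sum(base)
  out <- list()
  for (k in seq_along(lambda_grids)) {
    lab <- names(lambda_grids)[k]
    lambda <- lambda_grids[[lab]]
    sign_k <- ifelse(vapply(triples, `[[`, character(1L), k) == "up",
                     -1, 1)
    slope <- sign_k * stats::runif(n_proteins, slope_range[1L],
                                   slope_range[2L])
    r <- 1 + outer(slope, lambda - lambda_ref)
    if (any(r <= 0))
      stop("inconsistent plan: non-positive relative abundance; ",
           "reduce slopes or narrow the growth-rate grid")
    r <- r * exp(matrix(stats::rnorm(length(r), 0, noise_sd), nrow(r)))
    samples <- sprintf("%s%02d", lab, seq_along(lambda))
    frac <- r * base
    frac <- sweep(frac, 2L, colSums(frac), "/")
    ref <- base * exp(stats::rnorm(n_proteins, 0, noise_sd))
    ref <- ref / sum(ref)
    frac <- cbind(REF = ref, frac)
    dimnames(frac) <- list(protein_ids, c("REF", samples))
    out[[lab]] <- list(fractions = frac, samples = samples,
                       lambda = lambda)
  }
  list(series = out, planted = plan, reference_sample = "REF")
}
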