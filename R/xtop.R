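#' Hyperparameters for the xTop MAP estimator
#'
#' The xTop model for one protein writes each present log2 precursor
#' intensity as `y_ps = x_s + e_p + noise`, with `x_s` the log2 protein
#' intensity in sample `s`, `e_p = log2(efficiency)` the peptide-specific
#' detection efficiency, and independent Gaussian noise of per-peptide SD
#' `sigma_p`. The maximum a posteriori fit places a Gaussian prior of SD
#' `efficiency_prior_sd` (log2 units) on each `e_p`, a flat prior on the
#' `x_s`, and regularizes each `sigma_p^2` by shrinking it toward the
#' protein-wide residual variance with `noise_shrinkage` pseudo-observations
#' and flooring it at `noise_floor^2`.
#'
#' @param efficiency_prior_sd prior SD of log2 detection efficiencies
#'   (log2 units)
#' @param noise_floor lower bound on the peptide noise SD (log2 units);
#'   prevents a single self-consistent peptide from acquiring infinite
#'   weight
#' @param noise_shrinkage pseudo-observation count shrinking per-peptide
#'   variances toward the protein-wide residual variance
#' @param max_iter maximum coordinate-ascent sweeps
#' @param rel_tol convergence threshold on the maximum relative parameter
#'   change per sweep
#' @return list of class `xtop_hyperparams`
#' @export
xtop_hyperparams <- function(efficiency_prior_sd = 4, noise_floor = 0.1,
                             noise_shrinkage = 2, max_iter = 100L,
                             rel_tol = 1e-6) {
  vals <- c(efficiency_prior_sd, noise_floor, noise_shrinkage,
            max_iter, rel_tol)
  if (any(is.na(vals) | vals <= 0))
    stop("all xTop hyperparameters must be positive")
  structure(list(efficiency_prior_sd = efficiency_prior_sd,
                 noise_floor = noise_floor,
                 noise_shrinkage = noise_shrinkage,
                 max_iter = as.integer(max_iter),
                 rel_tol = rel_tol),
            class = "xtop_hyperparams")
}

#' Fit the xTop model and infer protein intensities
#'
#' For each protein independently (fit order never affects results), the
#' posterior of the multiplicative model `I_ps = I_s * eps_p * noise` is
#' maximized on log2 intensities over the present entries only, by block
#' coordinate ascent:
#'
#' 1. `x_s <- sum_p w_p (y_ps - e_p) / sum_p w_p`, with weights
#'    `w_p = 1 / sigma_p^2` -- the protein intensity is a consistency-
#'    weighted average of efficiency-corrected peptide intensities, so
#'    peptides that agree with the others across samples contribute most;
#' 2. `e_p <- (sum_s (y_ps - x_s)) / sigma_p^2 / (n_p / sigma_p^2 + 1/tau^2)`
#'    -- Gaussian shrinkage of each efficiency toward 1 (0 in log2);
#' 3. `sigma_p^2 <- (sum_s resid^2 + k * sigma_global^2) / (n_p + k)`,
#'    floored at the noise floor, with `sigma_global^2` the protein-wide
#'    residual variance and `k` the shrinkage pseudo-count.
#'
#' Missing entries are simply absent from the likelihood (missing-at-random
#' treatment; no censoring term). After every sweep the efficiencies are
#' re-anchored so that `max_p eps_p = 1`, i.e. intensities are expressed
#' relative to the best-detected (Top1-like) peptide; this also fixes the
#' near-degenerate `(x + c, e - c)` direction of the posterior, which
#' un-anchored coordinate ascent traverses only geometrically slowly.
#' When dropout splits a protein's peptide-sample detection graph into
#' disconnected components, each component is anchored to its own top
#' peptide (components share no sample, so their relative scale is not
#' identified by the data). Proteins with a single usable precursor
#' return that precursor's intensities verbatim.
#'
#' The fit is fully deterministic; `seed` only seeds the optional
#' initialization jitter (`jitter_sd > 0`), which is off by default.
#'
#' @param x a [peptide_matrix()]
#' @param hyper an [xtop_hyperparams()] object
#' @param include_shared include shared peptides (non-default behaviour)
#' @param seed integer seed for the optional jitter
#' @param jitter_sd SD (log2 units) of Gaussian jitter added to the
#'   initial sample intensities; 0 disables
#' @return list with `intensities` (proteins x samples matrix of linear
#'   xTop intensities, attribute `method = "xtop"`) and `models` (per
#'   protein: `log2_intensity`, `efficiency`, `sigma`, `weight`,
#'   `converged`, `iterations`)
#' @export
fit_xtop <- function(x, hyper = xtop_hyperparams(), include_shared = FALSE,
                     seed = NULL, jitter_sd = 0) {
  stopifnot(inherits(x, "peptide_matrix"),
            inherits(hyper, "xtop_hyperparams"))
  proteins <- inference_proteins(x, include_shared)
  out <- matrix(NA_real_, length(proteins), ncol(x$intensities),
                dimnames = list(proteins, x$samples))
  models <- vector("list", length(proteins))
  names(models) <- proteins
  if (jitter_sd > 0 && !is.null(seed)) set.seed(seed)
  for (i in seq_along(proteins)) {
    sub <- protein_peptides(x, proteins[i],
                            include_shared = include_shared)
    fit <- xtop_fit_protein(sub$intensities, hyper, jitter_sd)
    out[i, ] <- 2^fit$log2_intensity
    models[[i]] <- fit
  }
  n_fail <- sum(!vapply(models, `[[`, logical(1L), "converged"))
  if (n_fail > 0L)
    warning(n_fail, " protein(s) did not converge within max_iter; ",
            "last iterate returned (flagged in models)")
  list(intensities = structure(out, method = "xtop"), models = models)
}

# Fit one protein. m: precursors x samples, NA = missing, linear scale.
xtop_fit_protein <- function(m, hyper, jitter_sd = 0) {
  keep <- rowSums(!is.na(m)) > 0L
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("protein has no precursor present in any sample")
  if (nrow(m) == 1L) {
    return(list(log2_intensity = log2(m[1L, ]),
                efficiency = stats::setNames(1, rownames(m)),
                sigma = stats::setNames(hyper$noise_floor, rownames(m)),
                weight = stats::setNames(1 / hyper$noise_floor^2,
                                         rownames(m)),
                converged = TRUE, iterations = 0L))
  }
  y <- log2(m)
  present <- !is.na(y)
  n_p <- rowSums(present)
  covered <- colSums(present) > 0L
  tau2 <- hyper$efficiency_prior_sd^2
  s2_min <- hyper$noise_floor^2
  k <- hyper$noise_shrinkage

  # Connected components of the peptide-sample detection graph. Peptides
  # in different components share no sample, so their relative
  # efficiencies are set only by the prior; each component is anchored to
  # its own top peptide, otherwise the unpinned components creep along
  # their gauge direction and the sweep never converges.
  comp <- seq_len(nrow(y))
  repeat {
    changed <- FALSE
    for (s in which(covered)) {
      members <- which(present[, s])
      target <- min(comp[members])
      if (any(comp[members] != target)) {
        comp[comp %in% comp[members]] <- target
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sample_comp <- apply(present, 2L, function(det)
    if (any(det)) comp[which(det)[1L]] else NA_integer_)

  # init: x from the globally top-ranked precursor where present, else the
  # per-sample mean of present log2 intensities; e = 0; sigma global.
  means0 <- rowMeans(ifelse(present, y, 0))
  top <- which.max(means0)
  xs <- colMeans(y, na.rm = TRUE)
  xs[present[top, ]] <- y[top, present[top, ]]
  xs[!covered] <- NA_real_
  if (jitter_sd > 0)
    xs[covered] <- xs[covered] + stats::rnorm(sum(covered), 0, jitter_sd)
  e <- rep(0, nrow(y))
  resid <- sweep(y - rep(xs, each = nrow(y)), 1L, e)
  s2_global <- max(mean(resid[present]^2), s2_min)
  s2 <- rep(s2_global, nrow(y))

  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(hyper$max_iter)) {
    xs_old <- xs; e_old <- e; s2_old <- s2
    w <- 1 / s2
    # (i) sample intensities: weighted average over present precursors
    centered <- y - e  # y_ps - e_p (recycles e down columns)
    wm <- present * w
    xs <- colSums(ifelse(present, centered, 0) * w) / colSums(wm)
    xs[!covered] <- NA_real_
    # (ii) efficiencies with Gaussian shrinkage toward 0
    dev <- y - rep(xs, each = nrow(y))
    sum_dev <- rowSums(ifelse(present, dev, 0))
    e <- (sum_dev / s2) / (n_p / s2 + 1 / tau2)
    # (iii) per-peptide noise variances, shrunk and floored
    resid <- dev - e
    rss_p <- rowSums(ifelse(present, resid, 0)^2)
    s2_global <- sum(rss_p) / sum(n_p)
    s2 <- pmax((rss_p + k * s2_global) / (n_p + k), s2_min)
    # re-anchor every sweep: top efficiency = 1 in every connected
    # component. Besides fixing the reporting convention, this pins each
    # component's (x + c, e - c) gauge direction, along which plain
    # coordinate ascent creeps arbitrarily slowly.
    for (cc in unique(comp)) {
      e_max <- max(e[comp == cc])
      e[comp == cc] <- e[comp == cc] - e_max
      shift <- covered & !is.na(sample_comp) & sample_comp == cc
      xs[shift] <- xs[shift] + e_max
    }
    delta <- max(abs(c(xs - xs_old, e - e_old, sqrt(s2) - sqrt(s2_old))) /
                   pmax(abs(c(xs_old, e_old, sqrt(s2_old))), 1),
                 na.rm = TRUE)
    if (delta < hyper$rel_tol) { converged <- TRUE; break }
  }
  list(log2_intensity = xs,
       efficiency = stats::setNames(2^e, rownames(y)),
       sigma = stats::setNames(sqrt(s2), rownames(y)),
       weight = stats::setNames(1 / s2, rownames(y)),
       converged = converged, iterations = iter)
}
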