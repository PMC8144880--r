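#' Normalize mass fractions to a reference condition
#'
#' Relative abundances `r_is = phi_is / geomean(phi_i over the reference
#' samples)`. With a single reference sample, `r` is exactly 1 there by
#' construction; with reference replicates the geometric mean is used, in
#' line with the multiplicative treatment of intensity data throughout.
#' Proteins absent from every reference sample cannot be normalized and
#' are dropped (recorded in the `dropped` attribute).
#'
#' @param fractions proteins x samples mass-fraction matrix
#' @param reference_samples column names of the reference condition
#' @return relative-abundance matrix over the normalizable proteins
#' @export
normalize_to_reference <- function(fractions, reference_samples) {
  missing_samples <- setdiff(reference_samples, colnames(fractions))
  if (length(missing_samples) > 0L)
    stop("reference sample(s) not in matrix: ",
         paste(missing_samples, collapse = ", "))
  ref <- fractions[, reference_samples, drop = FALSE]
  geo <- apply(ref, 1L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else exp(mean(log(v)))
  })
  dropped <- rownames(fractions)[is.na(geo)]
  if (length(dropped) > 0L)
    message(length(dropped),
            " protein(s) absent from all reference samples were dropped")
  keep <- !is.na(geo)
  structure(fractions[keep, , drop = FALSE] / geo[keep],
            dropped = dropped)
}

#' Fit the linear growth-rate response of one protein
#'
#' Ordinary least squares of the relative abundance on the growth rate:
#' `r(lambda) = r_0 + s * lambda`. A negative slope means the protein's
#' relative abundance rises as growth slows, i.e. the protein is
#' *upregulated* under the limitation; a positive slope means
#' downregulation. Slopes with `|s| < slope_tol` (default 0, the pure sign
#' rule) are treated as downregulation.
#'
#' @param r relative abundances (missing values dropped)
#' @param lambda growth rates in 1/h, parallel to `r`
#' @param slope_tol absolute slope below which the response is treated as
#'   flat (classified "down")
#' @return list with `slope`, `intercept`, `response` (`"up"`, `"down"`,
#'   or `NA` when fewer than 3 points are available), and `n`
#' @export
fit_limitation_slope <- function(r, lambda, slope_tol = 0) {
  keep <- !is.na(r) & !is.na(lambda)
  r <- r[keep]; lambda <- lambda[keep]
  if (length(r) < 3L)
    return(list(slope = NA_real_, intercept = NA_real_,
                response = NA_character_, n = length(r)))
  fit <- stats::lm.fit(cbind(1, lambda), r)
  slope <- unname(fit$coefficients[2L])
  # snap floating-point noise on perfectly flat series to an exact zero,
  # so the s = 0 tie rule behaves as written
  if (abs(slope) < 1e-12 * max(1, abs(fit$coefficients[1L]))) slope <- 0
  list(slope = slope, intercept = unname(fit$coefficients[1L]),
       response = if (slope < -slope_tol) "up" else "down",
       n = length(r))
}

# Fixed mapping from the (C, A, R) response triple to the sector label.
SECTOR_MAP <- c("up.down.down" = "C",
                "down.up.down" = "A",
                "down.down.up" = "R",
                "up.up.down" = "S",
                "down.down.down" = "U",
                "up.down.up" = "C'",
                "down.up.up" = "A'",
                "up.up.up" = "S'")

#' Classify proteins into the eight proteome sectors
#'
#' Given relative-abundance matrices for the carbon (C), anabolic (A) and
#' translational (R) limitation series with their growth rates, each
#' protein with at least three data points in *every* series is assigned
#' one of the 2^3 = 8 sectors from the signs of its three fitted slopes
#' (e.g. C-sector = up in C-limitation, down in A and R; S'-sector = up in
#' all three). All other proteins go to the unclassified "X" sector.
#'
#' @param series named list with elements `C`, `A`, `R`; each a list with
#'   `r` (proteins x samples relative abundances) and `lambda` (growth
#'   rates per sample)
#' @param slope_tol forwarded to [fit_limitation_slope()]
#' @return data.frame of class `sector_assignment`: one row per protein
#'   with the sector label and, per series, slope / intercept / response
#' @export
classify_sectors <- function(series, slope_tol = 0) {
  if (!identical(sort(names(series)), c("A", "C", "R")))
    stop("series must be a named list with exactly C, A and R elements")
  for (lab in c("C", "A", "R")) {
    s <- series[[lab]]
    if (!is.matrix(s$r) || length(s$lambda) != ncol(s$r))
      stop("series ", lab, ": r must be a matrix with one growth rate ",
           "per column")
    if (any(s$lambda <= 0)) stop("series ", lab, ": growth rates must be > 0")
  }
  proteins <- sort(unique(unlist(lapply(series, function(s) rownames(s$r)))))
  out <- data.frame(protein_id = proteins, sector = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- proteins
  responses <- matrix(NA_character_, length(proteins), 3L,
                      dimnames = list(proteins, c("C", "A", "R")))
  for (lab in c("C", "A", "R")) {
    s <- series[[lab]]
    for (pid in intersect(proteins, rownames(s$r))) {
      fit <- fit_limitation_slope(s$r[pid, ], s$lambda,
                                  slope_tol = slope_tol)
      responses[pid, lab] <- fit$response
      out[pid, paste0("slope_", lab)] <- fit$slope
      out[pid, paste0("intercept_", lab)] <- fit$intercept
    }
  }
  triple <- paste(responses[, "C"], responses[, "A"], responses[, "R"],
                  sep = ".")
  sector <- unname(SECTOR_MAP[triple])
  sector[is.na(sector)] <- "X"
  out$sector <- sector
  class(out) <- c("sector_assignment", "data.frame")
  out
}

#' Aggregate mass fractions by proteome sector
#'
#' @param assignment a [classify_sectors()] result (or any data.frame with
#'   `protein_id` and `sector` columns)
#' @param fractions proteins x samples mass-fraction matrix
#' @return sectors x samples matrix of summed mass fractions; proteins of
#'   the matrix absent from the assignment count as unclassified (`X`).
#'   The derived row `O` is the sum of the C', A' and S' sectors.
#' @export
sector_mass_fractions <- function(assignment, fractions) {
  sec <- assignment$sector[match(rownames(fractions),
                                 assignment$protein_id)]
  sec[is.na(sec)] <- "X"
  levels <- c(unname(SECTOR_MAP), "X")
  out <- matrix(0, length(levels), ncol(fractions),
                dimnames = list(levels, colnames(fractions)))
  for (lab in levels)
    out[lab, ] <- colSums(fractions[sec == lab, , drop = FALSE],
                          na.rm = TRUE)
  rbind(out, O = colSums(out[c("C'", "A'", "S'"), , drop = FALSE]))
}
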