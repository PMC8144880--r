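test_that("mass fractions weight intensities by molecular weight and
          normalize each sample to 1", {
  info <- protein_info(c("P1", "P2"), c(1e4, 3e4))
  m <- make_fractions(matrix(c(5, 5), 2, 1), c("P1", "P2"))
  frac <- to_mass_fractions(m, info)
  expect_equal(unname(frac[, 1]), c(0.25, 0.75))

  solo <- make_fractions(matrix(c(7, NA), 2, 1), c("P1", "P2"))
  expect_equal(unname(to_mass_fractions(solo, info)["P1", 1]), 1)

  set.seed(11)
  big <- matrix(2^runif(250, 2, 20), 50, 5,
                dimnames = list(sprintf("P%02d", 1:50), NULL))
  big[sample(250, 30)] <- NA
  info50 <- protein_info(rownames(big), runif(50, 1e4, 1e5))
  frac50 <- to_mass_fractions(big, info50)
  expect_true(all(abs(colSums(frac50, na.rm = TRUE) - 1) < 1e-12))
  expect_silent(validate_mass_fractions(frac50, tol = 1e-9))

  allna <- make_fractions(matrix(NA_real_, 2, 1), c("P1", "P2"))
  expect_error(to_mass_fractions(allna, info), "zero total")
})

test_that("calibration is the identity when the matrix already matches
          the standard, assigns factor 1 to uncovered proteins, and
          removes planted per-protein biases exactly", {
  set.seed(21)
  phi <- matrix(runif(8), 4, 2,
                dimnames = list(paste0("P", 1:4), c("cal", "other")))
  phi <- sweep(phi, 2, colSums(phi), "/")
  std <- reference_standard(rownames(phi), phi[, "cal"], "cal")
  out <- calibrate_to_standard(phi, std)
  expect_equal(unclass(out)[, ], phi[, ], tolerance = 1e-12)

  # protein with no value in the calibration sample keeps factor 1
  phi2 <- phi
  phi2["P4", "cal"] <- NA
  phi2[, "cal"] <- phi2[, "cal"] / sum(phi2[, "cal"], na.rm = TRUE)
  out2 <- calibrate_to_standard(phi2, std)
  expect_equal(unname(attr(out2, "scaling_factors")["P4"]), 1)

  # planted multiplicative bias b_i: calibration must restore rho
  rho <- c(P1 = 0.4, P2 = 0.3, P3 = 0.2, P4 = 0.1)
  b <- c(2, 0.5, 3, 1.25)
  biased <- rho * b
  biased_frac <- make_fractions(cbind(cal = biased / sum(biased)),
                                names(rho))
  out3 <- calibrate_to_standard(
    biased_frac, reference_standard(names(rho), rho, "cal"))
  expect_equal(unname(out3[, "cal"]), unname(rho), tolerance = 1e-9)

  # idempotence: exact when the standard covers all calibrated proteins
  once <- calibrate_to_standard(biased_frac,
                                reference_standard(names(rho), rho, "cal"))
  twice <- calibrate_to_standard(once,
                                 reference_standard(names(rho), rho, "cal"))
  expect_equal(unclass(twice)[, ], unclass(once)[, ], tolerance = 1e-9)
  # ... and with partial coverage it is exact on the absolute scale
  once_abs <- calibrate_to_standard(phi2, std, renormalize = FALSE)
  twice_abs <- calibrate_to_standard(once_abs, std, renormalize = FALSE)
  expect_equal(unclass(twice_abs)[, ], unclass(once_abs)[, ],
               tolerance = 1e-9)

  # empty overlap is an error
  expect_error(
    calibrate_to_standard(phi, reference_standard("QQ", 0.5, "cal")),
    "no protein shared")
})

test_that("calibration uses the geometric mean across several
          calibration replicates", {
  phi <- make_fractions(cbind(c1 = c(0.01, 0.99), c2 = c(0.04, 0.96)),
                        c("P1", "P2"))
  std <- reference_standard("P1", 0.10, c("c1", "c2"))
  out <- calibrate_to_standard(phi, std, renormalize = FALSE)
  # divisor is geomean(0.01, 0.04) = 0.02 -> factor 5
  expect_equal(unname(attr(out, "scaling_factors")["P1"]), 5)
})

test_that("mass-fraction to concentration conversion is linear in phi and
          inversely proportional to length", {
  par <- concentration_params(3e6, mean_protein_length = 240)
  expect_equal(number_concentration(1e-5, 240, par), 30)
  expect_equal(number_concentration(0.1, 240, par), 3e5)
  expect_equal(number_concentration(0, 300, par), 0)
  expect_equal(number_concentration(2e-4, 300, par),
               2 * number_concentration(1e-4, 300, par))
  expect_equal(number_concentration(1e-4, 600, par),
               number_concentration(1e-4, 300, par) / 2)
  expect_error(number_concentration(0.1, -5, par), "> 0")
  # self-consistency: per-protein concentrations add up to the total
  set.seed(31)
  phi <- runif(20); phi <- phi / sum(phi)
  len <- sample(100:900, 20)
  par2 <- concentration_params(
    3e6, mean_protein_length = mean_protein_length(phi, len))
  expect_equal(sum(number_concentration(phi, len, par2)), 3e6)
})

test_that("complex concentration divides member concentrations by copy
          numbers and summarizes the spread", {
  info <- protein_info(c("P1", "P2"), c(3e4, 3e4), length = c(300, 300))
  par <- concentration_params(3e6, mean_protein_length = 300)
  # both members at concentration 100 -> estimates 100 and 100/2
  phi_val <- 100 / 3e6
  frac <- make_fractions(cbind(s1 = c(phi_val, phi_val)), c("P1", "P2"))
  cdef <- complex_definition("cpx", c("P1", "P2"), c(1L, 2L))
  res <- complex_concentration(frac, "s1", cdef, info, par)
  expect_equal(unname(res$estimates), c(100, 50))

  # perfectly stoichiometric members: zero spread
  frac2 <- make_fractions(cbind(s1 = c(2 * phi_val, phi_val)),
                          c("P1", "P2"))
  cdef2 <- complex_definition("cpx", c("P1", "P2"), c(2L, 1L))
  res2 <- complex_concentration(frac2, "s1", cdef2, info, par)
  expect_equal(res2$log10_interdecile_spread, 0)

  # log-normal scatter: spread matches a hand-rolled quantile computation
  set.seed(41)
  n <- 10
  ids <- sprintf("M%02d", 1:n)
  infoN <- protein_info(ids, rep(3e4, n), length = rep(300, n))
  noisy <- phi_val * exp(rnorm(n, 0, 0.3 * log(10)))
  fracN <- make_fractions(cbind(s1 = noisy), ids)
  cdefN <- complex_definition("big", ids, rep(1L, n))
  resN <- complex_concentration(fracN, "s1", cdefN, infoN, par)
  est <- sort(unname(resN$estimates))
  manual_q <- function(p) {  # type-7 interpolation, written out
    h <- (n - 1) * p + 1
    lo <- floor(h)
    est[lo] + (h - lo) * (est[min(lo + 1, n)] - est[lo])
  }
  expect_equal(resN$log10_interdecile_spread,
               log10(manual_q(0.95) / manual_q(0.05)), tolerance = 1e-12)

  # nothing detected: empty result with a warning
  fracNA <- make_fractions(cbind(s1 = c(NA_real_, NA_real_)),
                           c("P1", "P2"))
  expect_warning(res0 <- complex_concentration(fracNA, "s1", cdef, info,
                                               par), "no member")
  expect_length(res0$estimates, 0)
})

test_that("surface density and occupied-area fraction follow the direct
          geometric arithmetic", {
  expect_equal(surface_density(1000, 5), 200)
  expect_equal(surface_density(0, 3), 0)
  expect_error(surface_density(10, 0), "> 0")
  expect_equal(occupied_area_fraction(1e4, 2.6e-3),
               1e4 * pi * 1.3e-3^2, tolerance = 1e-12)
  expect_equal(round(occupied_area_fraction(1e4, 2.6e-3), 4), 0.0531)
})
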