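test_that("Beer-Lambert calibration inverts absorbance linearly", {
  cal <- calibration(0.01, 0)
  expect_equal(concentration_from_absorbance(1.47, cal), 147)
  expect_equal(concentration_from_absorbance(0.05, calibration(0.01, 0.05)), 0)
  expect_warning(concentration_from_absorbance(0.01, calibration(0.01, 0.05)),
                 "negative")
  expect_error(calibration(-1), "slope")
})

test_that("partition coefficient and its log behave as ratios", {
  p <- partition_coefficient(5, 5)
  expect_equal(p$P_ow, 1)
  expect_equal(p$logP, 0)
  expect_equal(partition_coefficient(8.02, 1)$logP, log10(8.02),
               tolerance = 1e-12)
  expect_equal(round(partition_coefficient(8.02, 1)$logP, 3), 0.904)
  expect_equal(round(partition_coefficient(3.32, 1)$logP, 3), 0.521)
  expect_error(partition_coefficient(0, 1), "positive")
  # scale covariance: P(c, ck) * k = 1
  for (k in c(0.1, 2, 17)) {
    expect_equal(partition_coefficient(3, 3 * k)$P_ow * k, 1,
                 tolerance = 1e-12)
  }
})

test_that("cohort aggregation records exclusions and both logP summaries", {
  samples <- data.frame(sample = 1:6,
                        c_oct = c(8, 8, 8, 8, 8, 8.12),
                        c_aq = 1)
  res <- aggregate_partition(samples)
  expect_equal(res$mean_P, 8.02)
  # identical samples: zero spread
  same <- data.frame(sample = 1:3, c_oct = 4, c_aq = 2)
  res2 <- aggregate_partition(same)
  expect_equal(res2$sd_P, 0)
  expect_equal(res2$mean_P, 2)
  # explicit exclusions are recorded, never silent
  res3 <- aggregate_partition(samples, exclusions = c(6))
  expect_equal(res3$excluded, 6)
  expect_equal(res3$n, 5)
  expect_equal(res3$mean_P, 8)
  expect_error(aggregate_partition(same, exclusions = 1:3), "retained")
  # mean-of-logs differs from log-of-mean for spread cohorts
  spread <- data.frame(sample = 1:3, c_oct = c(2, 8, 32), c_aq = 1)
  res4 <- aggregate_partition(spread)
  expect_equal(res4$mean_logP, log10(8), tolerance = 1e-12)
  expect_gt(res4$logP_of_mean, res4$mean_logP)
})

test_that("membrane-bound fraction reproduces the depletion percentages", {
  expect_equal(membrane_bound_fraction(147, 147), 0)
  expect_equal(membrane_bound_fraction(147, 55.86), 62)
  expect_equal(membrane_bound_fraction(147, 95.55), 35)
  # invariant to concentration units
  expect_equal(membrane_bound_fraction(147e-6, 55.86e-6), 62)
  expect_warning(membrane_bound_fraction(100, 110), "exceeds")
  expect_error(membrane_bound_fraction(0, 1), "c_initial")
})

test_that("inverse-Boltzmann PMF matches closed forms and round-trips", {
  z <- seq(-3, 3, by = 0.05)
  # uniform density: constant PMF
  u <- pmf_from_density(data.frame(z = z, rho = rep(2, length(z))))
  expect_equal(diff(range(u$pmf)), 0)
  # Gaussian density: quadratic PMF z^2 / (2 sigma^2) + const
  sig <- 0.7
  g <- pmf_from_density(data.frame(z = z, rho = exp(-z^2 / (2 * sig^2))))
  expect_equal(g$pmf - g$pmf[z == 0], z^2 / (2 * sig^2), tolerance = 1e-12)
  # round trip: exp(-pmf) proportional to rho
  rho <- 0.3 + abs(sin(z))
  p <- pmf_from_density(data.frame(z = z, rho = rho))
  expect_equal(exp(-p$pmf) / rho, rep(1, length(z)), tolerance = 1e-12)
  # non-positive densities are masked
  m <- pmf_from_density(data.frame(z = 1:3, rho = c(1, 0, 2)))
  expect_true(is.na(m$pmf[2]))
})

test_that("bundled synthetic density profiles run through the PMF chain", {
  pE <- read_profile(system.file("extdata", "synthetic_density_E.csv",
                                 package = "rbcswitch"))
  pZ <- read_profile(system.file("extdata", "synthetic_density_Z.csv",
                                 package = "rbcswitch"))
  expect_named(pE, c("z", "rho"))
  wE <- pmf_from_density(pE)
  wZ <- pmf_from_density(pZ)
  ratio <- partition_ratio_from_pmf(wZ, wE)
  # the Z profile carries less Boltzmann weight than the E profile
  expect_lt(ratio, 1)
  expect_gt(ratio, 0)
})

test_that("PMF partition ratio reproduces offset and well asymmetries", {
  z <- seq(-2, 2, by = 0.02)
  w <- data.frame(z = z, pmf = z^2)
  # identical profiles: ratio 1
  expect_equal(partition_ratio_from_pmf(w, w), 1, tolerance = 1e-12)
  # constant 0.4 kT offset: ratio exp(-0.4) ~ 0.67
  off <- transform(w, pmf = pmf + 0.4)
  expect_equal(partition_ratio_from_pmf(off, w), exp(-0.4), tolerance = 1e-12)
  # invariance to a common constant added to both profiles
  expect_equal(partition_ratio_from_pmf(transform(off, pmf = pmf + 3),
                                        transform(w, pmf = pmf + 3)),
               partition_ratio_from_pmf(off, w), tolerance = 1e-12)
  # aligning at a reference point removes a pure offset
  expect_equal(partition_ratio_from_pmf(off, w, align_at = 0), 1,
               tolerance = 1e-12)
  # two deep narrow wells, depths 13 vs 12 kT
  zz <- seq(-1.5, 1.5, by = 0.002)
  wellA <- data.frame(z = zz, pmf = -12 * exp(-zz^2 / (2 * 0.08^2)))
  wellB <- data.frame(z = zz, pmf = -13 * exp(-zz^2 / (2 * 0.08^2)))
  ratio <- partition_ratio_from_pmf(wellA, wellB)
  # independent quadrature oracle for the same Boltzmann integrals
  boltz <- function(d) stats::integrate(function(x)
    exp(d * exp(-x^2 / (2 * 0.08^2))), -1.5, 1.5, rel.tol = 1e-10)$value
  expect_equal(ratio, boltz(12) / boltz(13), tolerance = 1e-6)
  # Laplace approximation for deep narrow wells: ~ exp(-1) sqrt(13/12)
  expect_equal(ratio, exp(-1) * sqrt(13 / 12), tolerance = 0.05)
  # disjoint supports fail loudly
  far <- data.frame(z = z + 100, pmf = z^2)
  expect_error(partition_ratio_from_pmf(far, w), "overlap")
})
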