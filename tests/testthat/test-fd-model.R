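test_that("FRET-quenched time constant follows the Forster rate law", {
  # at r = R0 the transfer rate equals the intrinsic rate: lifetime halves
  expect_equal(fret_quenched_tau(16, 12.2, 12.2), 8)
  # zero-FRET limit
  expect_equal(fret_quenched_tau(16, 1e6, 12.2), 16, tolerance = 1e-12)
  # direct arithmetic for a fitted parameter set
  expect_equal(fret_quenched_tau(15.7, 18.8, 12.2),
               15.7 / (1 + (12.2 / 18.8)^6))
  # strictly increasing in r
  r <- seq(5, 40, by = 0.5)
  expect_true(all(diff(fret_quenched_tau(16, r, 14.9)) > 0))
  expect_error(fret_quenched_tau(-1, 10, 10), "positive")
  expect_error(fret_quenched_tau(16, 0, 10), "positive")
})

test_that("distance density has Gaussian peaks and unit mass", {
  d1 <- distance_distribution(15, 2)
  expect_equal(distance_density(d1, 15), 1 / (2 * sqrt(2 * pi)),
               tolerance = 1e-6)
  # normalization for a spread of valid parameter sets, incl. donor-only mass
  sets <- list(
    distance_distribution(15, 2),
    distance_distribution(c(30, 10), c(1, 1), c(0.5, 0.5)),
    distance_distribution(c(18.3, 12.7), c(2.5, 1.3), c(0.62, 0.38)),
    distance_distribution(c(23.7, 13.4), c(6.2, 6.5), c(0.4, 0.6),
                          donor_only_fraction = 0.08))
  for (d in sets)
    expect_equal(integrate_density(d), 1, tolerance = 1e-6)
  # mass within +/- 1 sigma of each mean, against an adaptive-quadrature
  # oracle on the exact truncated-Gaussian mixture
  d <- distance_distribution(c(18.3, 12.7), c(2.5, 1.3), c(0.62, 0.38))
  mass1 <- integrate(function(r) distance_density(d, r), 18.3 - 2.5,
                     18.3 + 2.5, rel.tol = 1e-10)$value
  oracle1 <- 0.62 * (pnorm(1) - pnorm(-1)) +
    0.38 * (pnorm(18.3 + 2.5, 12.7, 1.3) - pnorm(18.3 - 2.5, 12.7, 1.3))
  expect_equal(mass1, oracle1, tolerance = 1e-6)
})

test_that("constructors reject invalid models", {
  expect_error(donor_decay(c(1, 2, 3)), "1 or 2")
  expect_error(donor_decay(16, 0.9), "sum to 1")
  expect_error(donor_decay(-16), "positive")
  expect_error(distance_distribution(c(10, 20), c(1, 1), c(0.7, 0.7)),
               "sum to 1")
  expect_error(distance_distribution(10, -1), "positive")
  expect_error(distance_distribution(10, 1, donor_only_fraction = 1.5),
               "0, 1")
})

test_that("forward model matches the single-exponential closed form", {
  freqs <- seq(10, 200, by = 10)
  omega <- 2 * pi * freqs * 1e-3
  for (tau in c(2, 16)) {
    # sigma -> 0 at very long distance: effectively unquenched donor
    fr <- forward_response(donor_decay(tau),
                           distance_distribution(5000, 0.01), r0 = 12.2,
                           frequencies = freqs)
    expect_equal(fr$phase_deg, atan(omega * tau) * 180 / pi,
                 tolerance = 1e-9)
    expect_equal(fr$modulation, 1 / sqrt(1 + (omega * tau)^2),
                 tolerance = 1e-9)
  }
  # spot value quoted for tau = 16 ns at 10 MHz
  fr <- forward_response(donor_decay(16), distance_distribution(5000, 0.01),
                         r0 = 12.2, frequencies = 10)
  expect_equal(fr$phase_deg, 45.15, tolerance = 0.005)
  expect_equal(fr$modulation, 0.705, tolerance = 0.001)
})

test_that("sigma -> 0 converges to the discrete-distance mixture", {
  freqs <- default_frequencies()
  omega <- 2 * pi * freqs * 1e-3
  r0 <- 12.2
  taus <- fret_quenched_tau(15.5, c(18.3, 12.7), r0)
  # closed-form two-exponential mixture with intensity weights
  a <- c(0.62, 0.38)
  j <- sum(a * taus)
  n <- colSums(a * taus^2 %o% omega / (1 + outer(taus^2, omega^2))) / j
  d <- colSums(a * taus %o% rep(1, length(omega)) /
                 (1 + outer(taus^2, omega^2))) / j
  fr <- forward_response(donor_decay(15.5),
                         distance_distribution(c(18.3, 12.7), c(1e-3, 1e-3),
                                               a), r0, frequencies = freqs)
  expect_equal(fr$phase_deg, atan2(n, d) * 180 / pi, tolerance = 1e-5)
  expect_equal(fr$modulation, sqrt(n^2 + d^2), tolerance = 1e-7)
})

test_that("forward model agrees with the time-domain Fourier oracle", {
  freqs <- seq(10, 200, by = 10)
  cases <- list(
    list(tau = 15.7, rbar = 18.8, sigma = 3.5, r0 = 12.2),
    list(tau = 15.5, rbar = 12.7, sigma = 1.3, r0 = 12.2),
    list(tau = 15.6, rbar = 23.7, sigma = 6.2, r0 = 14.9),
    list(tau = 15.1, rbar = 13.6, sigma = 5.3, r0 = 14.9))
  for (cs in cases) {
    oracle <- td_oracle_response(cs$tau, 1, cs$rbar, cs$sigma, 1,
                                 r0 = cs$r0, frequencies = freqs)
    fr <- forward_response(donor_decay(cs$tau),
                           distance_distribution(cs$rbar, cs$sigma),
                           cs$r0, frequencies = freqs)
    expect_lt(max(abs(fr$phase_deg - oracle$phase_deg)), 0.1)
    expect_lt(max(abs(fr$modulation - oracle$modulation)), 0.002)
  }
  # two-Gaussian mixture with donor-only fraction and two-exponential donor
  oracle <- td_oracle_response(c(14, 2), c(0.7, 0.3), c(18.3, 12.7),
                               c(2.5, 1.3), c(0.62, 0.38), f_d = 0.08,
                               r0 = 12.2, frequencies = freqs)
  fr <- forward_response(donor_decay(c(14, 2), c(0.7, 0.3)),
                         distance_distribution(c(18.3, 12.7), c(2.5, 1.3),
                                               c(0.62, 0.38),
                                               donor_only_fraction = 0.08),
                         12.2, frequencies = freqs)
  expect_lt(max(abs(fr$phase_deg - oracle$phase_deg)), 0.1)
  expect_lt(max(abs(fr$modulation - oracle$modulation)), 0.002)
})

test_that("analytic and literal-Gaussian donor-only treatments agree", {
  freqs <- default_frequencies()
  dist <- distance_distribution(18.3, 2.5, donor_only_fraction = 0.15)
  fa <- forward_response(donor_decay(15.5), dist, 12.2, frequencies = freqs,
                         donor_only = "analytic")
  fg <- forward_response(donor_decay(15.5), dist, 12.2, frequencies = freqs,
                         donor_only = "gaussian150")
  expect_equal(fa$phase_deg, fg$phase_deg, tolerance = 1e-6)
  expect_equal(fa$modulation, fg$modulation, tolerance = 1e-6)
  ea <- apparent_efficiency(donor_decay(15.5), dist, 12.2)
  eg <- apparent_efficiency(donor_decay(15.5), dist, 12.2,
                            donor_only = "gaussian150")
  expect_equal(ea, eg, tolerance = 1e-6)
})

test_that("n/d columns obey the polar identity", {
  bg <- single_exp_background(default_frequencies())
  fr <- forward_response(donor_decay(16), distance_distribution(15, 3), 14.9,
                         instrument_model(t0 = 0.4, f_b = 0.1, bg),
                         default_frequencies())
  omega <- 2 * pi * fr$frequency_mhz * 1e-3
  phi <- fr$phase_deg * pi / 180 - omega * 0.4
  expect_equal(fr$modulation * sin(phi), fr$n, tolerance = 1e-12)
  expect_equal(fr$modulation * cos(phi), fr$d, tolerance = 1e-12)
})

test_that("apparent efficiency behaves as a FRET efficiency", {
  # Forster midpoint
  expect_equal(apparent_efficiency(donor_decay(16),
                                   distance_distribution(12.2, 1e-4), 12.2),
               0.5, tolerance = 1e-6)
  # donor-only population transfers nothing
  expect_equal(apparent_efficiency(donor_decay(16),
                                   distance_distribution(15, 2,
                                                         donor_only_fraction = 1),
                                   12.2), 0, tolerance = 1e-9)
  # quadrature oracle for a fitted parameter set
  integrand <- function(r) dnorm(r, 18.3, 2.5) / (1 + (12.2 / r)^6)
  z <- pnorm(18.3 + 15, 18.3, 2.5) - pnorm(max(0.01, 18.3 - 15), 18.3, 2.5)
  j_oracle <- integrate(integrand, max(0.01, 18.3 - 15), 18.3 + 15,
                        rel.tol = 1e-12)$value * 15.5 / z
  e_oracle <- 1 - j_oracle / 15.5
  expect_equal(apparent_efficiency(donor_decay(15.5),
                                   distance_distribution(18.3, 2.5), 12.2),
               e_oracle, tolerance = 1e-4)
  # strictly decreasing in mean distance
  es <- vapply(seq(8, 30, by = 1), function(r)
    apparent_efficiency(donor_decay(16), distance_distribution(r, 2), 14.9),
    0)
  expect_true(all(diff(es) < 0))
})

test_that("background/time-shift correction round-trips the forward model", {
  freqs <- default_frequencies()
  bg <- single_exp_background(freqs, tau_b = 2.5)
  inst <- instrument_model(t0 = 0.5, f_b = 0.2, bg)
  clean <- forward_response(donor_decay(16), distance_distribution(15, 3),
                            14.9, frequencies = freqs)
  dirty <- forward_response(donor_decay(16), distance_distribution(15, 3),
                            14.9, inst, freqs)
  fixed <- correct_response(dirty, inst)
  expect_equal(fixed$phase_deg, clean$phase_deg, tolerance = 1e-8)
  expect_equal(fixed$modulation, clean$modulation, tolerance = 1e-10)
  # identity with no background and no shift
  same <- correct_response(clean, instrument_model())
  expect_equal(same$phase_deg, clean$phase_deg, tolerance = 1e-12)
  # corrected single-exponential-plus-background returns to the circle
  single <- forward_response(donor_decay(16),
                             distance_distribution(5000, 0.01), 14.9,
                             inst, freqs)
  pt <- to_phasor(correct_response(single, inst), 10)
  expect_lt(abs(universal_circle_residual(pt)), 1e-8)
})

test_that("forward model enforces its configuration contract", {
  expect_error(forward_response(donor_decay(16),
                                distance_distribution(15, 2), 14.9,
                                instrument_model(f_b = 0.1),
                                frequencies = 10),
               "background phasor")
  bg <- single_exp_background(c(10, 20))
  expect_error(forward_response(donor_decay(16),
                                distance_distribution(15, 2), 14.9,
                                instrument_model(0, 0.1, bg),
                                frequencies = c(10, 30)),
               "missing at frequency 30")
  expect_error(forward_response(donor_decay(16),
                                distance_distribution(15, 2), 14.9,
                                frequencies = numeric()), "non-empty")
})

test_that("Gaussian FWHM identity", {
  expect_equal(gaussian_fwhm(1), 2 * sqrt(2 * log(2)))
  expect_equal(gaussian_fwhm(0), 0)
})
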