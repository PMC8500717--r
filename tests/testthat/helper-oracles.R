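# Independent oracles used to pin down expected values.  These deliberately
# avoid the package's frequency-domain code path: the decay is simulated in
# the time domain on a fine grid and Fourier-transformed numerically.

# Time-domain oracle for the frequency response of a donor decay quenched by
# Gaussian-distributed acceptor distances.
td_oracle_response <- function(tau, alpha, means = numeric(), sds = numeric(),
                               amps = numeric(), f_d = 0, r0 = 1,
                               frequencies = seq(10, 200, by = 10),
                               dt = 0.02, tmax = 20 * max(tau), n_r = 601) {
  t <- seq(0, tmax, by = dt)
  intensity <- numeric(length(t))
  for (k in seq_along(means)) {
    r <- seq(max(0.01, means[k] - 8 * sds[k]), means[k] + 8 * sds[k],
             length.out = n_r)
    w <- dnorm(r, means[k], sds[k])
    w <- w / pracma::trapz(r, w)
    for (i in seq_along(tau)) {
      tau_eff <- tau[i] / (1 + (r0 / r)^6)
      decay <- exp(-outer(t, 1 / tau_eff))          # time x r
      intensity <- intensity + (1 - f_d) * amps[k] * alpha[i] *
        apply(decay, 1, function(row) pracma::trapz(r, row * w))
    }
  }
  if (f_d > 0)
    for (i in seq_along(tau))
      intensity <- intensity + f_d * alpha[i] * exp(-t / tau[i])
  omega <- 2 * pi * frequencies * 1e-3
  total <- pracma::trapz(t, intensity)
  n <- vapply(omega, function(o) pracma::trapz(t, intensity * sin(o * t)),
              0) / total
  d <- vapply(omega, function(o) pracma::trapz(t, intensity * cos(o * t)),
              0) / total
  data.frame(frequency_mhz = frequencies,
             phase_deg = atan2(n, d) * 180 / pi,
             modulation = sqrt(n^2 + d^2))
}

# Piecewise adaptive integration of an evaluated distance density, split at
# the truncation edges of each component (where the density has jump
# discontinuities that defeat a single adaptive pass) and around the narrow
# donor-only spike at 150 A.
integrate_density <- function(d, upper = 200) {
  a <- pmax(0.01, d$mean - 6 * d$sd)
  b <- d$mean + 6 * d$sd
  breaks <- sort(unique(pmin(c(0, a, b, 149, 151, upper), upper)))
  total <- 0
  for (i in seq_len(length(breaks) - 1))
    total <- total + integrate(function(r) distance_density(d, r),
                               breaks[i], breaks[i + 1],
                               subdivisions = 2000, rel.tol = 1e-10,
                               abs.tol = 1e-12)$value
  total
}

# Ground-truth parameter vectors for the constructs whose fitted means are
# used throughout the recovery tests.
truth_mbp295_hh <- function(t0 = 0, f_b = 0.05) {
  fd_parameters(f_d = 0, tau_d1 = 15.5, alpha_1 = 1, tau_d2 = 2, r0 = 12.2,
                rbar1 = 18.3, sigma1 = 2.5, a2 = 0, rbar2 = 12.7,
                sigma2 = 1.3, t0 = t0, f_b = f_b)
}

truth_mbp295_tetac <- function(t0 = 0, f_b = 0.05) {
  fd_parameters(f_d = 0.08, tau_d1 = 15.6, alpha_1 = 1, tau_d2 = 2, r0 = 14.9,
                rbar1 = 23.7, sigma1 = 6.2, a2 = 0, rbar2 = 13.4,
                sigma2 = 6.5, t0 = t0, f_b = f_b)
}

truth_mbp322_tetac <- function(t0 = 0, f_b = 0.05) {
  fd_parameters(f_d = 0.08, tau_d1 = 15.1, alpha_1 = 1, tau_d2 = 2, r0 = 14.9,
                rbar1 = 13.6, sigma1 = 5.3, a2 = 0, rbar2 = 15.8,
                sigma2 = 5.5, t0 = t0, f_b = f_b)
}
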