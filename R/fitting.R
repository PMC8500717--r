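#' The 12-entry model parameter vector
#'
#' All model parameters of the frequency-domain tmFRET model live in a single
#' named vector: donor-only fraction `f_d`; donor decay `tau_d1`, `alpha_1`,
#' `tau_d2` (ns); Forster distance `r0` (A); first Gaussian `rbar1`, `sigma1`
#' (A); occupancy of the second component `a2`; second Gaussian `rbar2`,
#' `sigma2` (A); IRF time shift `t0` (ns); background fraction `f_b`.
#'
#' @param f_d,tau_d1,alpha_1,tau_d2,r0,rbar1,sigma1,a2,rbar2,sigma2,t0,f_b
#'   Parameter values; see Description for units.
#' @return A named numeric vector of class `fd_parameters`.
#' @export
fd_parameters <- function(f_d = 0, tau_d1 = 16, alpha_1 = 1, tau_d2 = 2,
                          r0 = 14.9, rbar1 = 20, sigma1 = 3, a2 = 0,
                          rbar2 = 13, sigma2 = 2, t0 = 0, f_b = 0) {
  p <- c(f_d = f_d, tau_d1 = tau_d1, alpha_1 = alpha_1, tau_d2 = tau_d2,
         r0 = r0, rbar1 = rbar1, sigma1 = sigma1, a2 = a2, rbar2 = rbar2,
         sigma2 = sigma2, t0 = t0, f_b = f_b)
  validate_fd_parameters(p)
  structure(p, class = "fd_parameters")
}

#' @rdname fd_parameters
#' @param p A named numeric vector with the 12 parameter names.
#' @export
validate_fd_parameters <- function(p) {
  need <- names(default_parameter_bounds()$lower)
  if (!all(need %in% names(p))) stop("missing parameters: ",
                                     paste(setdiff(need, names(p)), collapse = ", "))
  frac <- c("f_d", "alpha_1", "a2", "f_b")
  if (any(p[frac] < 0 | p[frac] > 1)) stop("fractions must lie in [0, 1]")
  pos <- c("tau_d1", "tau_d2", "r0", "rbar1", "sigma1", "rbar2", "sigma2")
  if (any(p[pos] <= 0)) stop("tau, r0, rbar and sigma must be positive")
  invisible(p)
}

#' Default box bounds for fitting
#'
#' @return A list with named vectors `lower` and `upper` covering the 12
#'   parameters. Fractions are bounded to `[0, 1]`; distances and lifetimes
#'   to generous physical ranges.
#' @export
default_parameter_bounds <- function() {
  lower <- c(f_d = 0, tau_d1 = 0.05, alpha_1 = 0, tau_d2 = 0.05, r0 = 1,
             rbar1 = 4, sigma1 = 0.1, a2 = 0, rbar2 = 4, sigma2 = 0.1,
             t0 = -5, f_b = 0)
  upper <- c(f_d = 1, tau_d1 = 50, alpha_1 = 1, tau_d2 = 50, r0 = 50,
             rbar1 = 60, sigma1 = 20, a2 = 1, rbar2 = 60, sigma2 = 20,
             t0 = 5, f_b = 0.8)
  list(lower = lower, upper = upper)
}

# Build model pieces from a parameter vector.
.decay_from <- function(p) {
  a1 <- unname(p["alpha_1"])
  if (a1 >= 1 - 1e-12) donor_decay(unname(p["tau_d1"]))
  else donor_decay(unname(c(p["tau_d1"], p["tau_d2"])), c(a1, 1 - a1))
}

.dist_from <- function(p) {
  a2 <- unname(p["a2"])
  if (a2 <= 1e-12) {
    distance_distribution(unname(p["rbar1"]), unname(p["sigma1"]),
                          donor_only_fraction = unname(p["f_d"]))
  } else if (a2 >= 1 - 1e-12) {
    distance_distribution(unname(p["rbar2"]), unname(p["sigma2"]),
                          donor_only_fraction = unname(p["f_d"]))
  } else {
    distance_distribution(unname(c(p["rbar1"], p["rbar2"])),
                          unname(c(p["sigma1"], p["sigma2"])),
                          c(1 - a2, a2),
                          donor_only_fraction = unname(p["f_d"]))
  }
}

#' Evaluate the forward model at a parameter vector
#'
#' @param p An [fd_parameters()] vector.
#' @param frequencies Modulation frequencies (MHz).
#' @param background_phasor Background phasor data frame, or `NULL`.
#' @param n_nodes Quadrature nodes per component.
#' @return A [frequency_response()].
#' @export
model_response <- function(p, frequencies, background_phasor = NULL,
                           n_nodes = 257) {
  forward_response(.decay_from(p), .dist_from(p), unname(p["r0"]),
                   instrument_model(unname(p["t0"]), unname(p["f_b"]),
                                    background_phasor),
                   frequencies, n_nodes = n_nodes)
}

#' Predicted apparent FRET efficiency at a parameter vector
#'
#' @inheritParams model_response
#' @return Efficiency in `[0, 1)`.
#' @export
model_efficiency <- function(p, n_nodes = 257) {
  apparent_efficiency(.decay_from(p), .dist_from(p), unname(p["r0"]),
                      n_nodes = n_nodes)
}

#' One measurement condition of a tmFRET experiment
#'
#' Bundles the lifetime data for one epoch of the experimental sequence
#' (donor-only, +acceptor, +ligand, reversal) with its optional steady-state
#' quenching measurement and background phasor.
#'
#' @param label One of `"donor_only"`, `"acceptor"`, `"acceptor_ligand"`
#'   (saturating ligand), `"subsaturating"`, `"reversal"`.
#' @param response A [frequency_response()].
#' @param steady_state_e Optional apparent FRET efficiency measured by
#'   steady-state quenching for this condition.
#' @param background_phasor Optional background phasor data frame (needed to
#'   fit `f_b > 0`).
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(label, response, steady_state_e = NULL,
                                 background_phasor = NULL) {
  label <- match.arg(label, c("donor_only", "acceptor", "acceptor_ligand",
                              "subsaturating", "reversal"))
  stopifnot(inherits(response, "frequency_response"))
  structure(list(label = label, response = response,
                 steady_state_e = steady_state_e,
                 background_phasor = background_phasor),
            class = "experiment_condition")
}

#' Chi-square weighting scheme
#'
#' Measurement standard deviations used to weight phase, modulation and
#' steady-state efficiency residuals. The instrument precision is not part of
#' the data files, so these are stated defaults, typical for frequency-domain
#' instruments, and configurable.
#'
#' @param s_phase Phase delay s.d. (degrees).
#' @param s_mod Modulation ratio s.d.
#' @param s_e Steady-state efficiency s.d. (one efficiency observation
#'   carries the weight of one frequency point).
#' @return A list of class `chi_weights`.
#' @export
chi_weights <- function(s_phase = 0.2, s_mod = 0.004, s_e = 0.01) {
  stopifnot(s_phase > 0, s_mod > 0, s_e > 0)
  structure(list(s_phase = s_phase, s_mod = s_mod, s_e = s_e),
            class = "chi_weights")
}

.condition_residuals <- function(p, condition, weights, n_nodes = 257) {
  pred <- model_response(p, condition$response$frequency_mhz,
                         condition$background_phasor, n_nodes = n_nodes)
  res <- c((condition$response$phase_deg - pred$phase_deg) / weights$s_phase,
           (condition$response$modulation - pred$modulation) / weights$s_mod)
  if (!is.null(condition$steady_state_e))
    res <- c(res, (condition$steady_state_e - model_efficiency(p, n_nodes)) /
               weights$s_e)
  res
}

#' Chi-square objective for one condition
#'
#' Sum of squared weighted residuals over phase delay, modulation ratio, and
#' (when present) the steady-state quenching efficiency.
#'
#' @param p An [fd_parameters()] vector.
#' @param condition An [experiment_condition()].
#' @param weights A [chi_weights()].
#' @return Non-negative objective value; zero for noiseless data evaluated at
#'   the generating parameters.
#' @export
chi_square <- function(p, condition, weights = chi_weights()) {
  sum(.condition_residuals(p, condition, weights)^2)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Fit the model to one condition
#'
#' Bounded Levenberg-Marquardt minimization of [chi_square()] over the free
#' parameters, optionally from multiple Latin-hypercube starting points; the
#' best of the starts is reported. Non-convergence is flagged in the result,
#' never silent.
#'
#' @param condition An [experiment_condition()].
#' @param init Full [fd_parameters()] vector; fixed parameters keep these
#'   values.
#' @param free Character vector of parameter names allowed to vary.
#' @param weights A [chi_weights()].
#' @param bounds Bounds list as from [default_parameter_bounds()].
#' @param n_starts Number of starts (1 = from `init` only; additional starts
#'   are Latin-hypercube draws within bounds).
#' @param seed Seed for the multi-start draws.
#' @param n_nodes Quadrature nodes per component.
#' @return A list of class `fd_fit` with elements `parameters` (full vector
#'   with fitted values), `free`, `chi2`, `residuals`, `n_obs`, `converged`,
#'   `info` and `label`.
#' @export
fit_condition <- function(condition, init, free,
                          weights = chi_weights(),
                          bounds = default_parameter_bounds(),
                          n_starts = 4, seed = 1234, n_nodes = 257) {
  stopifnot(inherits(condition, "experiment_condition"))
  validate_fd_parameters(init)
  if (!all(free %in% names(init))) stop("unknown free parameter name")
  n_obs <- 2 * nrow(condition$response) +
    as.integer(!is.null(condition$steady_state_e))
  if (n_obs < length(free))
    stop("fewer observations than free parameters")
  lower <- bounds$lower[free]
  upper <- bounds$upper[free]

  resid_fn <- function(x) {
    p <- init
    p[free] <- .clamp(x, lower, upper)
    .condition_residuals(p, condition, weights, n_nodes)
  }

  starts <- list(.clamp(unname(init[free]), lower, upper))
  if (n_starts > 1) {
    old <- .Random.seed_save()
    set.seed(seed)
    u <- lhs::randomLHS(n_starts - 1, length(free))
    .Random.seed_restore(old)
    for (i in seq_len(n_starts - 1))
      starts[[i + 1]] <- lower + u[i, ] * (upper - lower)
  }

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = unname(lower), upper = unname(upper), fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed for condition '",
                          condition$label, "'")
  out <- init
  out[free] <- .clamp(best$par, lower, upper)
  structure(list(parameters = out, free = free, chi2 = best$deviance,
                 residuals = best$fvec, n_obs = n_obs,
                 converged = best$info %in% 1:4, info = best$message,
                 label = condition$label),
            class = "fd_fit")
}

# save/restore the RNG state so seeded internals do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv()))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}

#' Donor-only fraction assumed for an acceptor chemistry
#'
#' Cysteine-reactive Cu2+-TETAC labeling leaves about 8% of donors without an
#' acceptor (calibrated with a long-R0 cysteine-reactive quencher); labeling
#' of di-histidine sites with 100 uM Cu2+ is taken as complete.
#'
#' @param acceptor `"cu_tetac"` or `"cu_dihis"`.
#' @return The default donor-only fraction `f_d`.
#' @export
default_donor_only_fraction <- function(acceptor = c("cu_tetac", "cu_dihis")) {
  switch(match.arg(acceptor), cu_tetac = 0.08, cu_dihis = 0)
}

#' Staged fitting protocol across an experimental sequence
#'
#' Reproduces the parameter-freezing protocol used to analyze a tmFRET
#' lifetime experiment:
#' \enumerate{
#'   \item donor-only: free `(tau_d1, t0, f_b)` with `f_d = 1`,
#'     `alpha_1 = 1` (set `two_exponential = TRUE` to also free
#'     `(alpha_1, tau_d2)` for nonexponential donors);
#'   \item acceptor, no ligand: free `(rbar1, sigma1, t0, f_b)` with
#'     `a2 = 0` and `f_d` fixed by the acceptor chemistry;
#'   \item acceptor + saturating ligand: free `(rbar2, sigma2, t0, f_b)`
#'     with `a2 = 1`, `f_d` inherited;
#'   \item subsaturating ligand (any number of conditions): free
#'     `(a2, t0, f_b)` with both Gaussians frozen;
#'   \item reversal: free `(f_d, t0, f_b)`.
#' }
#' Frozen values flow forward from earlier stages. `t0` and `f_b` are refit
#' per condition since they absorb instrument drift.
#'
#' @param conditions List of [experiment_condition()] objects. Must contain a
#'   `donor_only` condition; later stages require their prerequisites.
#' @param r0 Forster distance (A) for the donor-acceptor pair, determined
#'   independently from spectra (see [forster_radius()]).
#' @param acceptor Acceptor chemistry, sets the default `f_d`.
#' @param f_d_acceptor Override for the donor-only fraction in acceptor
#'   conditions.
#' @param init Optional full initial [fd_parameters()] vector.
#' @param two_exponential Fit a two-exponential donor decay at stage 1.
#' @param weights,bounds,n_starts,seed,n_nodes Passed to [fit_condition()].
#' @return A list of class `fd_protocol_fit`: one `fd_fit` per condition (in
#'   protocol order) plus `parameters`, the final consolidated vector.
#' @export
fit_protocol <- function(conditions, r0,
                         acceptor = c("cu_tetac", "cu_dihis"),
                         f_d_acceptor = NULL, init = NULL,
                         two_exponential = FALSE,
                         weights = chi_weights(),
                         bounds = default_parameter_bounds(),
                         n_starts = 4, seed = 1234, n_nodes = 257) {
  acceptor <- match.arg(acceptor)
  if (is.null(f_d_acceptor)) f_d_acceptor <- default_donor_only_fraction(acceptor)
  labels <- vapply(conditions, `[[`, character(1), "label")
  if (length(labels) == 0 || labels[1] != "donor_only" || !"donor_only" %in% labels)
    stop("protocol error: the sequence must begin with a donor_only condition")

  if (is.null(init)) init <- fd_parameters(r0 = r0)
  p <- init
  p["r0"] <- r0
  fits <- list()

  take <- function(lbl) conditions[labels == lbl]

  # stage 1: donor only
  p["f_d"] <- 1; p["alpha_1"] <- 1
  free1 <- if (two_exponential) c("tau_d1", "alpha_1", "tau_d2", "t0", "f_b")
           else c("tau_d1", "t0", "f_b")
  f1 <- fit_condition(take("donor_only")[[1]], p, free1, weights, bounds,
                      n_starts, seed, n_nodes)
  p <- f1$parameters
  fits[["donor_only"]] <- f1

  # stage 2: acceptor, no ligand
  cond2 <- take("acceptor")
  if (length(cond2)) {
    p2 <- p
    p2["f_d"] <- f_d_acceptor; p2["a2"] <- 0
    f2 <- fit_condition(cond2[[1]], p2, c("rbar1", "sigma1", "t0", "f_b"),
                        weights, bounds, n_starts, seed + 1, n_nodes)
    p <- f2$parameters
    fits[["acceptor"]] <- f2
  }

  # stage 3: saturating ligand
  cond3 <- take("acceptor_ligand")
  if (length(cond3)) {
    if (!"acceptor" %in% names(fits))
      stop("protocol error: saturating-ligand stage requires the acceptor stage")
    p3 <- p
    p3["a2"] <- 1
    f3 <- fit_condition(cond3[[1]], p3, c("rbar2", "sigma2", "t0", "f_b"),
                        weights, bounds, n_starts, seed + 2, n_nodes)
    p <- f3$parameters
    p["a2"] <- 1
    fits[["acceptor_ligand"]] <- f3
  }

  # stage 4: subsaturating ligand (both Gaussians frozen)
  cond4 <- take("subsaturating")
  if (length(cond4)) {
    if (!all(c("acceptor", "acceptor_ligand") %in% names(fits)))
      stop("protocol error: subsaturating stage requires both parent stages")
    for (i in seq_along(cond4)) {
      p4 <- p
      p4["a2"] <- 0.5
      f4 <- fit_condition(cond4[[i]], p4, c("a2", "t0", "f_b"),
                          weights, bounds, n_starts, seed + 3 + i, n_nodes)
      fits[[paste0("subsaturating", if (length(cond4) > 1) i else "")]] <- f4
    }
  }

  # stage 5: reversal
  cond5 <- take("reversal")
  if (length(cond5)) {
    p5 <- p
    p5["a2"] <- 0
    f5 <- fit_condition(cond5[[1]], p5, c("f_d", "t0", "f_b"),
                        weights, bounds, n_starts, seed + 9, n_nodes)
    fits[["reversal"]] <- f5
  }

  structure(c(fits, list(parameters = p)), class = "fd_protocol_fit")
}

#' Equilibrium constant and free energy from a two-state occupancy
#'
#' Interprets the occupancy `A2` of the second (ligand-bound) conformation as
#' a two-state equilibrium: `K = A2 / (1 - A2)` and `dG = -ln K` in units of
#' kT (positive when the second state is the minority).
#'
#' @param a2 Occupancy of the second state, strictly inside `(0, 1)`.
#' @return A list with elements `k` and `dg_kt`.
#' @examples
#' occupancy_to_equilibrium(0.38)
#' @export
occupancy_to_equilibrium <- function(a2) {
  if (any(a2 <= 0) || any(a2 >= 1))
    stop("a2 must lie strictly inside (0, 1)")
  k <- a2 / (1 - a2)
  list(k = k, dg_kt = -log(k))
}

#' @export
print.fd_fit <- function(x, ...) {
  cat("tmFRET fit:", x$label, "\n")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  cat("  chi2 =", format(x$chi2, digits = 5), "over", x$n_obs, "observations\n")
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  print(round(unclass(x$parameters)[x$free], 4))
  invisible(x)
}
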