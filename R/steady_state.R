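#' Steady-state fluorescence time course
#'
#' A time series of fluorescence intensity with reagent-addition annotations
#' (e.g. acceptor application, reducing agent, chelator), the raw material of
#' a steady-state quenching experiment.
#'
#' @param time Time (s), strictly increasing.
#' @param intensity Fluorescence intensity (arbitrary units), non-negative.
#' @param events Data frame with columns `time` (s) and `label` marking
#'   reagent additions; may be empty.
#' @return A data frame of class `time_course` with the events attached as
#'   attribute `events`.
#' @export
time_course <- function(time, intensity,
                        events = data.frame(time = numeric(), label = character())) {
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (!all(c("time", "label") %in% names(events)))
    stop("events needs columns time and label")
  out <- data.frame(time_s = time, intensity = intensity)
  attr(out, "events") <- events
  class(out) <- c("time_course", "data.frame")
  out
}

#' Fraction of fluorescence unquenched after a reagent addition
#'
#' `F = mean(intensity after event) / mean(intensity before event)`, with an
#' optional constant background subtracted from both windows. The default
#' windows are the last 5 samples before the event and samples 3-8 after it,
#' leaving out the first post-event samples to allow for mixing dead time
#' (< 10 s).
#'
#' @param trace A [time_course()].
#' @param event Label of the event (must appear in the trace's events).
#' @param before Number of samples immediately before the event to average.
#' @param after Integer range (length 2) of post-event sample indices to
#'   average; defaults to `c(3, 8)`.
#' @param background Constant background intensity to subtract.
#' @return A list with `value` (fraction unquenched), `se` (propagated from
#'   the window standard errors), and the window sizes.
#' @export
fraction_unquenched <- function(trace, event, before = 5, after = c(3, 8),
                                background = 0) {
  stopifnot(inherits(trace, "time_course"))
  ev <- attr(trace, "events")
  i <- match(event, ev$label)
  if (is.na(i)) stop("event '", event, "' not found in trace annotations")
  t_ev <- ev$time[i]
  pre_idx <- which(trace$time_s < t_ev)
  post_idx <- which(trace$time_s >= t_ev)
  pre_idx <- utils::tail(pre_idx, before)
  post_idx <- post_idx[seq(after[1], after[2])]
  post_idx <- post_idx[!is.na(post_idx)]
  if (length(pre_idx) < 3 || length(post_idx) < 3)
    stop("averaging windows around '", event, "' contain fewer than 3 samples")
  b <- trace$intensity[pre_idx] - background
  a <- trace$intensity[post_idx] - background
  f <- mean(a) / mean(b)
  se <- abs(f) * sqrt((stats::sd(a) / sqrt(length(a)) / mean(a))^2 +
                        (stats::sd(b) / sqrt(length(b)) / mean(b))^2)
  list(value = f, se = se, n_before = length(pre_idx), n_after = length(post_idx))
}

#' Corrected FRET efficiency from paired quenching measurements
#'
#' `E = 1 - F_cys / F_no_cys` corrects the fraction unquenched measured on
#' the acceptor-site construct (`F_cys`, or `F_HH` for di-histidine sites)
#' for nonspecific losses measured on the control construct lacking the
#' acceptor site (`F_no_cys`). Uncertainty is obtained by Monte-Carlo
#' resampling of the two input means and standard errors (default 1e6
#' cycles).
#'
#' @param f_cys,f_no_cys Lists with elements `mean` and `sem` (as returned,
#'   up to renaming, by [fraction_unquenched()]).
#' @param cycles Monte-Carlo cycles.
#' @param seed Seed for the resampling.
#' @return A list with `e` (point estimate), `se` (Monte-Carlo standard
#'   error), and `cycles`.
#' @export
fret_efficiency_corrected <- function(f_cys, f_no_cys, cycles = 1e6,
                                      seed = 1234) {
  if (f_no_cys$mean <= 0) stop("f_no_cys must be positive")
  e_hat <- 1 - f_cys$mean / f_no_cys$mean
  old <- .Random.seed_save()
  set.seed(seed)
  fc <- stats::rnorm(cycles, f_cys$mean, f_cys$sem)
  fn <- stats::rnorm(cycles, f_no_cys$mean, f_no_cys$sem)
  .Random.seed_restore(old)
  keep <- fn > 0
  e_mc <- 1 - fc[keep] / fn[keep]
  list(e = e_hat, se = stats::sd(e_mc), cycles = cycles)
}

#' FRET efficiency at a discrete distance
#'
#' The Forster relation `E(r) = 1 / (1 + (r/R0)^6)`.
#'
#' @param r Donor-acceptor distance (A).
#' @param r0 Forster distance (A).
#' @return Efficiency in (0, 1).
#' @export
forster_efficiency <- function(r, r0) {
  stopifnot(all(r > 0), all(r0 > 0))
  1 / (1 + (r / r0)^6)
}

#' Invert the Forster relation: distance from efficiency
#'
#' `R = R0 (1/E - 1)^(1/6)`, the inverse of [forster_efficiency()].
#'
#' @param e Efficiency, strictly inside (0, 1).
#' @param r0 Forster distance (A).
#' @return Distance (A).
#' @examples
#' forster_invert(0.5, 14.9) # = R0
#' @export
forster_invert <- function(e, r0) {
  if (any(e <= 0) || any(e >= 1)) stop("e must lie strictly inside (0, 1)")
  stopifnot(all(r0 > 0))
  r0 * (1 / e - 1)^(1 / 6)
}

#' Single-exponential decay fit of a time course
#'
#' Least-squares fit of `A exp(-t / tau) + C`, as used for photobleaching
#' time constants. Non-decaying traces are flagged rather than silently
#' returning a boundary fit.
#'
#' @param trace A [time_course()] with at least 10 points.
#' @return A list with `tau` (s), `se` (standard error of `tau`), `a`, `c`,
#'   `flagged` (TRUE when the trace does not decay), and the `nls` fit.
#' @export
exp_decay_fit <- function(trace) {
  stopifnot(inherits(trace, "time_course"))
  if (nrow(trace) < 10) stop("at least 10 points required")
  t <- trace$time_s
  y <- trace$intensity
  n3 <- max(3, nrow(trace) %/% 10)
  decaying <- mean(utils::head(y, n3)) > mean(utils::tail(y, n3))
  start <- list(a = max(y) - min(y), tau = diff(range(t)) / 3, c = min(y))
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(-t / tau) + c, start = start,
                               lower = c(a = 0, tau = 1e-9, c = -Inf),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    # degenerate (typically non-decaying) trace: flag, do not fail
    return(list(tau = NA_real_, se = NA_real_, a = NA_real_, c = NA_real_,
                flagged = TRUE, fit = NULL))
  }
  s <- summary(fit)$coefficients
  list(tau = s["tau", "Estimate"], se = s["tau", "Std. Error"],
       a = s["a", "Estimate"], c = s["c", "Estimate"],
       flagged = !decaying, fit = fit)
}

#' Hill fit of a dose-response curve
#'
#' Least-squares fit of `response = x^h / (x^h + K^h)` (maximal response
#' fixed at 1, appropriate for fraction-in-state data where the saturating
#' condition defines occupancy 1; set `free_amplitude = TRUE` to also fit a
#' maximal amplitude).
#'
#' @param dose Concentrations (uM), at least 3 points spanning the
#'   transition.
#' @param response Fractional response at each dose.
#' @param free_amplitude Fit a free maximal amplitude.
#' @return A list with `k_half` (uM), `hill`, their standard errors, the
#'   `amplitude` (1 unless freed), and the `nls` fit.
#' @examples
#' d <- c(50, 100, 200, 400, 800, 1600)
#' hill_fit(d, d / (d + 393))
#' @export
hill_fit <- function(dose, response, free_amplitude = FALSE) {
  if (length(dose) < 3) stop("at least 3 dose points required")
  if (diff(range(dose)) <= 0) stop("degenerate dose range")
  start <- list(k = stats::median(dose), h = 1)
  if (free_amplitude) {
    fit <- minpack.lm::nlsLM(response ~ a * dose^h / (dose^h + k^h),
                             start = c(start, a = max(response)),
                             lower = c(k = 1e-9, h = 0.1, a = 0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    fit <- minpack.lm::nlsLM(response ~ dose^h / (dose^h + k^h),
                             start = start, lower = c(k = 1e-9, h = 0.1),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  s <- summary(fit)$coefficients
  list(k_half = s["k", "Estimate"], k_se = s["k", "Std. Error"],
       hill = s["h", "Estimate"], hill_se = s["h", "Std. Error"],
       amplitude = if (free_amplitude) s["a", "Estimate"] else 1,
       fit = fit)
}
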