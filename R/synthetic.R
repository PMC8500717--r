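#' Noise model for synthetic measurements
#'
#' Gaussian measurement noise applied independently to phase delay and
#' modulation ratio, multiplicative noise on steady-state intensities, and a
#' per-pixel dispersion used when emulating imaging data for phasor
#' analysis. The defaults match the chi-square weighting defaults so that
#' reduced chi-square is ~1 on default-noise synthetic data.
#'
#' @param s_phase Phase delay s.d. (degrees).
#' @param s_mod Modulation ratio s.d.
#' @param s_intensity Fractional intensity noise for time courses.
#' @param s_pixel Per-pixel phasor dispersion (applied to d and n).
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(s_phase = 0.2, s_mod = 0.004, s_intensity = 0.01,
                        s_pixel = 0.005) {
  stopifnot(s_phase >= 0, s_mod >= 0, s_intensity >= 0, s_pixel >= 0)
  structure(list(s_phase = s_phase, s_mod = s_mod,
                 s_intensity = s_intensity, s_pixel = s_pixel),
            class = "noise_model")
}

#' Default modulation frequency grid
#'
#' Harmonics of a 10 MHz pulsed-excitation repetition rate, 10-200 MHz.
#'
#' @return Numeric vector of frequencies (MHz).
#' @export
default_frequencies <- function() seq(10, 200, by = 10)

#' Background phasor of a single-exponential background fluorophore
#'
#' Autofluorescence backgrounds have short lifetimes (2-3 ns); this builds
#' the background phasor table for such a background at the given
#' frequencies.
#'
#' @param frequencies Modulation frequencies (MHz).
#' @param tau_b Background lifetime (ns).
#' @return A background-phasor data frame for [instrument_model()].
#' @export
single_exp_background <- function(frequencies, tau_b = 2.5) {
  omega <- 2 * pi * frequencies * 1e-3
  data.frame(frequency_mhz = frequencies,
             phase_deg = atan(omega * tau_b) * 180 / pi,
             modulation = 1 / sqrt(1 + (omega * tau_b)^2))
}

#' Generate a synthetic frequency-domain dataset
#'
#' Evaluates the forward model at a ground-truth parameter vector and adds
#' independent Gaussian noise to phase and modulation. With zero noise the
#' output equals [model_response()] exactly. The ground truth, noise model
#' and seed are attached as attributes so every dataset is regenerable.
#'
#' @param truth An [fd_parameters()] vector.
#' @param frequencies Modulation frequencies (MHz).
#' @param noise A [noise_model()].
#' @param seed RNG seed.
#' @param background_phasor Background phasor; defaults to a 2.5 ns
#'   single-exponential background when `truth["f_b"] > 0`, else none.
#' @return A [frequency_response()] with attributes `truth`, `noise`,
#'   `seed`, `background_phasor`.
#' @export
generate_fd_dataset <- function(truth, frequencies = default_frequencies(),
                                noise = noise_model(), seed = 1,
                                background_phasor = NULL) {
  validate_fd_parameters(truth)
  if (is.null(background_phasor) && truth["f_b"] > 0)
    background_phasor <- single_exp_background(frequencies)
  resp <- model_response(truth, frequencies, background_phasor)
  old <- .Random.seed_save()
  set.seed(seed)
  resp$phase_deg <- resp$phase_deg +
    stats::rnorm(nrow(resp), 0, noise$s_phase)
  resp$modulation <- resp$modulation +
    stats::rnorm(nrow(resp), 0, noise$s_mod)
  .Random.seed_restore(old)
  resp$n <- NULL
  resp$d <- NULL
  attr(resp, "truth") <- truth
  attr(resp, "noise") <- noise
  attr(resp, "seed") <- seed
  attr(resp, "background_phasor") <- background_phasor
  resp
}

#' Generate a full synthetic experimental sequence
#'
#' Emits the measurement epochs of a tmFRET lifetime experiment with a
#' shared ground truth: donor-only, acceptor without ligand, any number of
#' subsaturating-ligand conditions, saturating ligand, and reversal. Each
#' condition draws its own small `(t0, f_b)` instrument drift, carries the
#' background phasor it was generated with, and (optionally) a noisy
#' steady-state efficiency.
#'
#' @param truth An [fd_parameters()] vector holding the shared parameters
#'   (donor decay, `r0`, both Gaussians). `truth["f_d"]` is the donor-only
#'   fraction of the acceptor conditions; `truth["a2"]` is ignored in favor
#'   of `a2_subsaturating`.
#' @param a2_subsaturating Occupancies of the closed state at the
#'   subsaturating conditions (may be empty).
#' @param frequencies Modulation frequencies (MHz).
#' @param noise A [noise_model()].
#' @param seed RNG seed; the whole sequence is a pure function of
#'   `(truth, a2_subsaturating, noise, seed)`.
#' @param t0_sd S.d. of the per-condition IRF time shift draw (ns).
#' @param f_b_range Range of the per-condition background fraction draw.
#' @param steady_state Attach a noisy steady-state efficiency (s.d.
#'   `chi_weights()$s_e`) to each acceptor-bearing condition.
#' @return A list of [experiment_condition()]s with attribute `truth`.
#' @export
generate_experiment_sequence <- function(truth, a2_subsaturating = numeric(),
                                         frequencies = default_frequencies(),
                                         noise = noise_model(), seed = 1,
                                         t0_sd = 0.2, f_b_range = c(0.02, 0.1),
                                         steady_state = TRUE) {
  validate_fd_parameters(truth)
  if (any(a2_subsaturating < 0 | a2_subsaturating > 1))
    stop("subsaturating occupancies must lie in [0, 1]")
  bg <- single_exp_background(frequencies)
  s_e <- noise$s_intensity  # steady-state efficiency noise

  old <- .Random.seed_save()
  set.seed(seed)
  specs <- list(list(label = "donor_only", f_d = 1, a2 = 0))
  specs <- c(specs, list(list(label = "acceptor",
                              f_d = unname(truth["f_d"]), a2 = 0)))
  for (a2 in a2_subsaturating)
    specs <- c(specs, list(list(label = "subsaturating",
                                f_d = unname(truth["f_d"]), a2 = a2)))
  specs <- c(specs, list(list(label = "acceptor_ligand",
                              f_d = unname(truth["f_d"]), a2 = 1)))
  specs <- c(specs, list(list(label = "reversal", f_d = 1, a2 = 0)))

  conditions <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    p <- truth
    p["f_d"] <- sp$f_d
    p["a2"] <- sp$a2
    p["t0"] <- truth["t0"] + stats::rnorm(1, 0, t0_sd)
    p["f_b"] <- stats::runif(1, f_b_range[1], f_b_range[2])
    cond_seed <- seed * 1000L + i
    resp <- generate_fd_dataset(p, frequencies, noise, cond_seed, bg)
    e_obs <- NULL
    if (steady_state && sp$label %in% c("acceptor", "subsaturating",
                                        "acceptor_ligand"))
      e_obs <- model_efficiency(p) + stats::rnorm(1, 0, s_e)
    conditions[[i]] <- experiment_condition(sp$label, resp,
                                            steady_state_e = e_obs,
                                            background_phasor = bg)
    attr(conditions[[i]], "truth") <- p
  }
  .Random.seed_restore(old)
  attr(conditions, "truth") <- truth
  conditions
}

#' Emulate a per-pixel phasor cloud for one condition
#'
#' Fluorescence-lifetime imaging represents each pixel as a point in phasor
#' space; a condition appears as a cluster whose centroid is the aggregate
#' phasor. This emulates such a cluster, at reduced scale, by scattering
#' independent Gaussian dispersion around the condition's aggregate phasor
#' coordinates.
#'
#' @param response The condition's [frequency_response()] (corrected).
#' @param frequency Modulation frequency (MHz) of the phasor plot.
#' @param n_pixels Number of pixels to emulate.
#' @param noise A [noise_model()]; `s_pixel` sets the per-pixel dispersion.
#' @param seed RNG seed.
#' @param group Group label for the cloud.
#' @return A `phasor_point` data frame with `n_pixels` rows.
#' @export
generate_phasor_pixels <- function(response, frequency = 10, n_pixels = 256,
                                   noise = noise_model(), seed = 1,
                                   group = NA_character_) {
  center <- to_phasor(response, frequency, group)
  old <- .Random.seed_save()
  set.seed(seed)
  out <- data.frame(frequency_mhz = frequency,
                    d = center$d + stats::rnorm(n_pixels, 0, noise$s_pixel),
                    n = center$n + stats::rnorm(n_pixels, 0, noise$s_pixel),
                    group = group)
  .Random.seed_restore(old)
  class(out) <- c("phasor_point", "data.frame")
  out
}

#' Generate a synthetic steady-state time course
#'
#' Step-wise fluorescence trace with exponential settling after each reagent
#' addition (mixing dead time < 10 s), optional slow photobleaching, and
#' multiplicative measurement noise.
#'
#' @param baseline Initial intensity (a.u.).
#' @param events Data frame with columns `time` (s), `label`, and `level`
#'   (target intensity as a fraction of baseline after the event, in
#'   `[0, 1.2]`).
#' @param duration Total duration (s).
#' @param dt Sampling interval (s).
#' @param settle_tau Settling time constant after an event (s).
#' @param bleach_tau Photobleaching time constant (s); `Inf` disables.
#' @param noise A [noise_model()]; `s_intensity` is used.
#' @param seed RNG seed.
#' @return A [time_course()].
#' @export
generate_timecourse <- function(baseline = 1, events = NULL, duration = 300,
                                dt = 2, settle_tau = 3, bleach_tau = Inf,
                                noise = noise_model(), seed = 1) {
  if (is.null(events))
    events <- data.frame(time = numeric(), label = character(),
                         level = numeric())
  if (nrow(events) && (any(events$level < 0) || any(events$level > 1.2)))
    stop("event levels must lie in [0, 1.2]")
  t <- seq(0, duration, by = dt)
  level <- rep(1, length(t))
  cur <- 1
  for (i in seq_len(nrow(events))) {
    after <- t >= events$time[i]
    level[after] <- events$level[i] +
      (cur - events$level[i]) * exp(-(t[after] - events$time[i]) / settle_tau)
    cur <- events$level[i]
  }
  y <- baseline * level * exp(-t / bleach_tau)
  old <- .Random.seed_save()
  set.seed(seed)
  y <- y * (1 + stats::rnorm(length(y), 0, noise$s_intensity))
  .Random.seed_restore(old)
  time_course(t, pmax(y, 0), events[, c("time", "label")])
}

#' Generate synthetic donor emission and acceptor absorption spectra
#'
#' Gaussian-shaped spectra on a 1 nm grid. When `target_r0` is supplied the
#' acceptor amplitude is rescaled in closed form (J is linear in the
#' acceptor spectrum, R0 ~ J^(1/6)) so that [forster_radius()] on the pair
#' returns the target.
#'
#' @param donor_peak,donor_width Donor emission peak and s.d. (nm).
#' @param acceptor_peak,acceptor_width Acceptor absorption peak and s.d.
#'   (nm).
#' @param acceptor_eps Peak molar absorptivity (M^-1 cm^-1).
#' @param wavelengths Wavelength grid (nm).
#' @param target_r0 Optional target Forster distance (A).
#' @param q,eta,kappa2 Quantum yield, refractive index and orientation
#'   factor used when solving for `target_r0`.
#' @return A list with `donor` and `acceptor` [spectrum_data()] objects.
#' @export
generate_spectra <- function(donor_peak = 450, donor_width = 35,
                             acceptor_peak = 550, acceptor_width = 60,
                             acceptor_eps = 300,
                             wavelengths = seq(350, 750, by = 1),
                             target_r0 = NULL, q = 0.8, eta = 1.33,
                             kappa2 = 2 / 3) {
  stopifnot(donor_width > 0, acceptor_width > 0)
  donor <- spectrum_data(wavelengths,
                         exp(-0.5 * ((wavelengths - donor_peak) / donor_width)^2),
                         "emission")
  acc_shape <- exp(-0.5 * ((wavelengths - acceptor_peak) / acceptor_width)^2)
  acceptor <- spectrum_data(wavelengths, acceptor_eps * acc_shape, "absorption")
  if (!is.null(target_r0)) {
    j <- overlap_integral(donor, acceptor)
    if (j <= 0) stop("spectra do not overlap; cannot hit a target R0")
    scale <- (target_r0 / forster_radius(j, q, eta, kappa2))^6
    acceptor <- spectrum_data(wavelengths, acceptor_eps * scale * acc_shape,
                              "absorption")
  }
  list(donor = donor, acceptor = acceptor)
}

#' Generate a toy protein structure for rotamer-sampler tests
#'
#' `"helix"` builds an ideal polyalanine alpha-helix (1.5 A rise and 100
#' degree twist per residue, CA radius 2.3 A) with full N/CA/C/O/CB
#' backbones: sites on it are solvent-exposed, so probe sampling accepts at
#' a high rate. `"buried"` surrounds the same helix with a tight shell of
#' dummy atoms so that every rotamer clashes, for exercising the buried-site
#' error path.
#'
#' @param kind `"helix"` or `"buried"`.
#' @param n_res Number of residues.
#' @param path Optional path for the PDB file; defaults to a tempfile.
#' @return A `pdb` object (also written to `path`).
#' @export
generate_toy_structure <- function(kind = c("helix", "buried"), n_res = 20,
                                   path = tempfile(fileext = ".pdb")) {
  kind <- match.arg(kind)
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  lines <- character(0)
  serial <- 0L
  emit <- function(elety, resno, xyz) {
    serial <<- serial + 1L
    sprintf("ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
            serial, elety, resno, xyz[1], xyz[2], xyz[3],
            substr(elety, 1, 1))
  }
  ca <- function(i) c(radius * cos(twist * i), radius * sin(twist * i),
                      rise * i)
  for (i in seq_len(n_res)) {
    cai <- ca(i)
    # approximate backbone neighbors along the helical path
    ni <- cai + 0.6 * .unit(ca(i - 0.5) - cai) + c(0, 0, -0.9)
    ci <- cai + 0.6 * .unit(ca(i + 0.5) - cai) + c(0, 0, 0.9)
    oi <- ci + c(0, 0, 1.23) * sign(1)
    cbi <- as.numeric(.ideal_cb(ni, cai, ci))
    lines <- c(lines, emit("N", i, ni), emit("CA", i, cai), emit("C", i, ci),
               emit("O", i, oi), emit("CB", i, cbi))
  }
  if (kind == "buried") {
    # tight cage of dummy atoms around the helix surface
    zs <- seq(-2, n_res * rise + 2, by = 1.5)
    for (z in zs) for (ang in seq(0, 2 * pi - 0.3, by = 0.3)) {
      lines <- c(lines, emit("X", 9000 + round(z * 10) %% 999,
                             c(7 * cos(ang), 7 * sin(ang), z)))
    }
  }
  writeLines(c(lines, "END"), path)
  read_structure(path)
}
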