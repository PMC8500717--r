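test_that("chi-square is zero at the truth and grows away from it", {
  truth <- truth_mbp295_hh(t0 = 0.3, f_b = 0.08)
  bg <- single_exp_background(default_frequencies())
  resp <- generate_fd_dataset(truth, noise = noise_model(0, 0, 0, 0),
                              seed = 1, background_phasor = bg)
  cond <- experiment_condition("acceptor", resp, background_phasor = bg)
  expect_equal(chi_square(truth, cond), 0, tolerance = 1e-18)

  # local single-parameter perturbations strictly increase the objective
  for (pm in c("rbar1", "sigma1", "t0", "f_b", "tau_d1")) {
    for (delta in c(-0.05, 0.05)) {
      p <- truth
      p[pm] <- p[pm] + delta
      expect_gt(chi_square(p, cond), 1e-4)
    }
  }

  # bit-for-bit deterministic
  p <- truth
  p["rbar1"] <- 19
  expect_identical(chi_square(p, cond), chi_square(p, cond))
})

test_that("noiseless single-condition fits recover the generating values", {
  truth <- truth_mbp295_hh(t0 = 0.2, f_b = 0.06)
  bg <- single_exp_background(default_frequencies())
  resp <- generate_fd_dataset(truth, noise = noise_model(0, 0, 0, 0),
                              seed = 1, background_phasor = bg)
  cond <- experiment_condition("acceptor", resp,
                               steady_state_e = model_efficiency(truth),
                               background_phasor = bg)
  init <- truth
  init[c("rbar1", "sigma1", "t0", "f_b")] <- c(15, 4, 0, 0.02)
  fit <- fit_condition(cond, init, c("rbar1", "sigma1", "t0", "f_b"),
                       n_starts = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters["rbar1"]), 18.3, tolerance = 1e-4)
  expect_equal(unname(fit$parameters["sigma1"]), 2.5, tolerance = 1e-3)
  expect_equal(unname(fit$parameters["t0"]), 0.2, tolerance = 1e-4)
  expect_equal(unname(fit$parameters["f_b"]), 0.06, tolerance = 1e-4)
  expect_lt(fit$chi2, 1e-8)
})

test_that("donor-only lifetimes are recovered from noisy data", {
  # single-exponential free Acd
  truth <- fd_parameters(f_d = 1, tau_d1 = 16, alpha_1 = 1, t0 = 0.1,
                         f_b = 0.05)
  bg <- single_exp_background(default_frequencies())
  resp <- generate_fd_dataset(truth, seed = 21, background_phasor = bg)
  cond <- experiment_condition("donor_only", resp, background_phasor = bg)
  fit <- fit_condition(cond, fd_parameters(f_d = 1),
                       c("tau_d1", "t0", "f_b"), n_starts = 2)
  expect_equal(unname(fit$parameters["tau_d1"]), 16, tolerance = 0.01)

  # double-exponential free Anap: a background-free cuvette measurement
  # (a free 2-3 ns background component is not identifiable next to a
  # 1.3/3.3 ns decay, so free-dye characterization fixes f_b = 0)
  truth2 <- fd_parameters(f_d = 1, tau_d1 = 1.3, alpha_1 = 0.76,
                          tau_d2 = 3.3, t0 = 0.1, f_b = 0)
  resp2 <- generate_fd_dataset(truth2, seed = 22, background_phasor = bg)
  cond2 <- experiment_condition("donor_only", resp2, background_phasor = bg)
  init2 <- fd_parameters(f_d = 1, tau_d1 = 1, alpha_1 = 0.6, tau_d2 = 5)
  fit2 <- fit_condition(cond2, init2,
                        c("tau_d1", "alpha_1", "tau_d2", "t0"),
                        n_starts = 4)
  expect_equal(unname(fit2$parameters["tau_d1"]), 1.3, tolerance = 0.05)
  expect_equal(unname(fit2$parameters["tau_d2"]), 3.3, tolerance = 0.05)
  expect_equal(unname(fit2$parameters["alpha_1"]), 0.76, tolerance = 0.05)
})

test_that("fit_condition enforces its preconditions", {
  bg <- single_exp_background(c(10, 20))
  resp <- frequency_response(c(10, 20), c(40, 60), c(0.7, 0.4))
  cond <- experiment_condition("donor_only", resp, background_phasor = bg)
  expect_error(fit_condition(cond, fd_parameters(),
                             c("tau_d1", "tau_d2", "alpha_1", "t0", "f_b",
                               "rbar1")),
               "fewer observations")
  expect_error(fit_condition(cond, fd_parameters(), "not_a_parameter"),
               "unknown free parameter")
})

test_that("the staged protocol recovers a noiseless sequence exactly", {
  truth <- truth_mbp295_hh()
  conds <- generate_experiment_sequence(truth,
                                        a2_subsaturating = c(0.38, 0.60),
                                        noise = noise_model(0, 0, 0, 0),
                                        seed = 3, t0_sd = 0,
                                        f_b_range = c(0.05, 0.05))
  fit <- fit_protocol(conds, r0 = 12.2, acceptor = "cu_dihis", n_starts = 2)
  expect_equal(unname(fit$donor_only$parameters["tau_d1"]), 15.5,
               tolerance = 1e-5)
  expect_equal(unname(fit$acceptor$parameters["rbar1"]), 18.3,
               tolerance = 1e-4)
  expect_equal(unname(fit$acceptor$parameters["sigma1"]), 2.5,
               tolerance = 1e-3)
  expect_equal(unname(fit$acceptor_ligand$parameters["rbar2"]), 12.7,
               tolerance = 1e-4)
  expect_equal(unname(fit$acceptor_ligand$parameters["sigma2"]), 1.3,
               tolerance = 1e-3)
  expect_equal(unname(fit$subsaturating1$parameters["a2"]), 0.38,
               tolerance = 1e-4)
  expect_equal(unname(fit$subsaturating2$parameters["a2"]), 0.60,
               tolerance = 1e-4)
  expect_equal(unname(fit$reversal$parameters["f_d"]), 1, tolerance = 1e-3)
})

test_that("the protocol demands a leading donor-only condition", {
  truth <- truth_mbp295_hh()
  conds <- generate_experiment_sequence(truth, a2_subsaturating = 0.5,
                                        seed = 4)
  labels <- vapply(conds, `[[`, "", "label")
  no_donor <- conds[labels != "donor_only"]
  expect_error(fit_protocol(no_donor, r0 = 12.2, acceptor = "cu_dihis"),
               "protocol error")
  # subsaturating without its parent stages is also a protocol error
  sub_only <- conds[labels %in% c("donor_only", "subsaturating")]
  expect_error(fit_protocol(sub_only, r0 = 12.2, acceptor = "cu_dihis"),
               "protocol error")
})

test_that("the TETAC donor-only fraction default is applied at stage 2", {
  expect_equal(default_donor_only_fraction("cu_tetac"), 0.08)
  expect_equal(default_donor_only_fraction("cu_dihis"), 0)
  truth <- truth_mbp295_tetac()
  conds <- generate_experiment_sequence(truth,
                                        noise = noise_model(0, 0, 0, 0),
                                        seed = 5, t0_sd = 0)
  fit <- fit_protocol(conds, r0 = 14.9, acceptor = "cu_tetac", n_starts = 2)
  expect_equal(unname(fit$acceptor$parameters["f_d"]), 0.08)
  expect_equal(unname(fit$acceptor$parameters["rbar1"]), 23.7,
               tolerance = 1e-3)
})

test_that("stage-4 occupancy has a unique minimum on [0, 1]", {
  truth <- truth_mbp295_hh()
  conds <- generate_experiment_sequence(truth, a2_subsaturating = 0.38,
                                        noise = noise_model(0, 0, 0, 0),
                                        seed = 6, t0_sd = 0,
                                        f_b_range = c(0.05, 0.05))
  sub <- conds[[3]]
  p <- attr(sub, "truth")
  # 1-D profile of the objective over a2 with everything else at truth
  a2_grid <- seq(0.02, 0.98, by = 0.02)
  prof <- vapply(a2_grid, function(a2) {
    q <- p; q["a2"] <- a2
    chi_square(q, sub)
  }, 0)
  expect_equal(a2_grid[which.min(prof)], 0.38, tolerance = 0.021)
  # strictly decreasing then increasing around the minimum
  k <- which.min(prof)
  expect_true(all(diff(prof[1:k]) < 0))
  expect_true(all(diff(prof[k:length(prof)]) > 0))
})

test_that("occupancy maps to equilibrium constant and free energy", {
  eq <- occupancy_to_equilibrium(0.5)
  expect_equal(eq$k, 1)
  expect_equal(eq$dg_kt, 0)
  eq38 <- occupancy_to_equilibrium(0.38)
  expect_equal(eq38$k, 0.38 / 0.62)
  expect_equal(eq38$dg_kt, -log(0.38 / 0.62))
  eq60 <- occupancy_to_equilibrium(0.60)
  expect_equal(eq60$k, 1.5)
  expect_equal(eq60$dg_kt, -log(1.5))
  expect_error(occupancy_to_equilibrium(0), "strictly inside")
  expect_error(occupancy_to_equilibrium(1), "strictly inside")
})
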