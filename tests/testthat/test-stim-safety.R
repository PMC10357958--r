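test_that("excursion potential matches the closed form and its limits", {
  m <- excursion_model(0.5, 2, 1, 0.5, 0.5)
  # zero current gives exactly zero
  expect_identical(predict_excursion(m, 0, 1, 1), 0)
  # frozen scalar arithmetic: 0.5 * ln(3)
  expect_equal(predict_excursion(m, 1, 1, 1), 0.5 * log(3))
  expect_equal(predict_excursion(m, 1, 1, 1), 0.5493061, tolerance = 1e-6)
  # small-argument linearization V ~ a * arg
  arg <- 1e-6
  i_small <- (arg / 2)  # b=2, k2=1, t=z=1
  expect_equal(predict_excursion(m, i_small, 1, 1), 0.5 * arg,
               tolerance = 1e-4)
  # strictly increasing in each argument
  expect_true(all(diff(predict_excursion(m, c(1, 2, 4), 1, 1)) > 0))
  expect_true(all(diff(predict_excursion(m, 1, c(1, 2, 4), 1)) > 0))
  expect_true(all(diff(predict_excursion(m, 1, 1, c(1, 2, 4))) > 0))
})

test_that("unit conventions are enforced, never silently converted", {
  m <- ref_excursion_model()
  expect_error(
    predict_excursion(m, 1, 1, 1, units = c(i = "mA", t = "us", z = "kohm")),
    "mismatch")
  expect_error(excursion_model(0.5, 2, 1, 0.5, 0.5,
                               units_decl = c(i = "uA", t = "us", z = "furlong")),
               "not a supported unit")
  # matching declaration passes through
  expect_equal(
    predict_excursion(m, 1, 1, 1, units = c(i = "uA", t = "us", z = "kohm")),
    predict_excursion(m, 1, 1, 1))
})

test_that("current-limit inversion round-trips through the forward model", {
  set.seed(101)
  for (rep in 1:10) {
    m <- excursion_model(runif(1, 0.2, 1), exp(runif(1, -6, 1)),
                         runif(1, 0.5, 2), runif(1, 0.2, 1),
                         runif(1, 0.2, 1))
    t_pw <- runif(1, 50, 500)
    z <- runif(1, 5, 200)
    e_mc <- -runif(1, 0.3, 1.5)
    i_lim <- current_limit_from_model(m, e_mc, t_pw, z)
    expect_equal(predict_excursion(m, i_lim, t_pw, z), abs(e_mc),
                 tolerance = 1e-10)
  }
  # worked inverse of the frozen forward example
  m0 <- excursion_model(0.5, 2, 1, 0.5, 0.5)
  expect_equal(current_limit_from_model(m0, 0.5 * log(3), 1, 1), 1,
               tolerance = 1e-12)
})

test_that("diameter-scaled limit is algebraically consistent with the direct inversion", {
  set.seed(3)
  m <- ref_excursion_model()
  for (rep in 1:10) {
    alpha <- exp(runif(1, -3, 3))
    d1 <- runif(1, 0.5, 2)
    lim <- safety_limits(-0.6, alpha_coeff = alpha, d1_exp = d1)
    d <- runif(1, 20e-6, 2e-3)
    t_pw <- runif(1, 50, 500)
    i_scaled <- current_limit_vs_diameter(lim, m, d, t_pw)
    z_kohm <- alpha * d^(-d1) / 1000  # brute-force substitution
    i_direct <- current_limit_from_model(m, -0.6, t_pw, z_kohm)
    expect_equal(i_scaled, i_direct, tolerance = 1e-10)
  }
})

test_that("current limit falls with pulse width and impedance, grows with diameter", {
  m <- ref_excursion_model()
  lim <- safety_limits(-0.6, alpha_coeff = 0.05, d1_exp = 1.3)
  t_grid <- seq(50, 1000, by = 25)
  z_grid <- seq(5, 300, by = 5)
  d_grid <- seq(30e-6, 2e-3, length.out = 40)
  expect_true(all(diff(current_limit_from_model(m, -0.6, t_grid, 30)) < 0))
  expect_true(all(diff(current_limit_from_model(m, -0.6, 200, z_grid)) < 0))
  expect_true(all(diff(current_limit_vs_diameter(lim, m, d_grid, 200)) > 0))
  # raising Z (the in vivo condition relative to benchtop) lowers the limit
  expect_lt(current_limit_from_model(m, -0.6, 200, 60),
            current_limit_from_model(m, -0.6, 200, 30))
})

test_that("missing diameter scaling is reported with a remedy", {
  m <- ref_excursion_model()
  lim <- safety_limits(-0.6)
  expect_error(current_limit_vs_diameter(lim, m, 1e-4, 200),
               "fit_diameter_scaling")
})

test_that("Shannon limit matches the worked example and scales exactly", {
  # D = 200 um, t_pw = 200 us, k = 1.85: Q ~ 0.1491 uC, I ~ 745.6 uA
  i <- shannon_limit(200e-6, 200e-6, 1.85)
  expect_equal(i * 1e6, 745.667, tolerance = 1e-4)
  q_uc <- i * 200e-6 * 1e6
  expect_equal(q_uc, 0.149133, tolerance = 1e-4)
  # exact linear-in-D and 1/t scalings
  expect_equal(shannon_limit(400e-6, 200e-6), 2 * shannon_limit(200e-6, 200e-6))
  expect_equal(shannon_limit(200e-6, 400e-6), shannon_limit(200e-6, 200e-6) / 2)
})

test_that("Shannon limit agrees with the independent charge-density equation", {
  # independent oracle: solve log10(Q/A) = k - log10(Q) numerically
  for (d in c(50e-6, 200e-6, 1e-3)) {
    for (k in c(1.5, 1.85, 2.0)) {
      a_cm2 <- pi * (d * 100)^2 / 4
      q_uc <- uniroot(function(q) log10(q / a_cm2) - (k - log10(q)),
                      c(1e-8, 1e4), tol = 1e-14)$root
      t_pw <- 2e-4
      expect_equal(shannon_limit(d, t_pw, k), q_uc * 1e-6 / t_pw,
                   tolerance = 1e-6)
    }
  }
})

test_that("the excursion model is recovered from noise-free and noisy datasets", {
  truth <- ref_excursion_model()
  g <- ref_excursion_grids()
  init <- excursion_model(0.3, 0.01, 0.8, 0.6, 0.4)
  truth_vec <- unlist(truth[c("a_scale", "b_coeff", "k2_exp", "k4_exp",
                              "k6_exp")])

  ds0 <- gen_excursion_dataset(truth, g$i, g$t, g$z,
                               noise_spec("additive_gaussian", 0))
  expect_equal(nrow(ds0), 60)
  fit0 <- fit_excursion_model(ds0, init, seed = 1)
  expect_lt(max(abs(fit0$estimates$value / truth_vec - 1)), 1e-3)

  ds <- gen_excursion_dataset(truth, g$i, g$t, g$z,
                              noise_spec("additive_gaussian", 0.005,
                                         seed = child_seed(11, 1)))
  fit <- fit_excursion_model(ds, init, seed = 11)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimates$value / truth_vec - 1)), 0.15)
  # determinism under the seed
  fit2 <- fit_excursion_model(ds, init, seed = 11)
  expect_identical(fit$estimates$value, fit2$estimates$value)
})

test_that("rank-deficient or narrow excursion designs are rejected", {
  truth <- ref_excursion_model()
  ds_one_i <- gen_excursion_dataset(truth, 50, c(20, 50, 100, 200, 500),
                                    c(10, 30, 100, 300),
                                    noise_spec("additive_gaussian", 0))
  expect_error(fit_excursion_model(ds_one_i, truth), "single value")
  ds_narrow <- gen_excursion_dataset(truth, c(50, 60, 70, 80, 90),
                                     c(50, 100, 200, 500), c(10, 30, 100),
                                     noise_spec("additive_gaussian", 0))
  expect_error(fit_excursion_model(ds_narrow, truth), "decade")
  small <- excursion_dataset(c(10, 100), c(50, 500), c(10, 10), c(0.1, 0.5))
  expect_error(fit_excursion_model(small, truth), "20 rows")
})

test_that("model-vs-Shannon comparison tables are dense, deterministic and directional", {
  m <- ref_excursion_model()
  lim <- safety_limits(-0.6, alpha_coeff = 0.05, d1_exp = 1.3,
                       shannon_k = 1.85)
  d <- c(50e-6, 200e-6, 1e-3)
  t <- c(100e-6, 200e-6, 500e-6, 1e-3)
  tab <- compare_to_shannon(m, lim, d, t)
  expect_equal(nrow(tab), length(d) * length(t))
  expect_identical(tab, compare_to_shannon(m, lim, d, t))
  expect_equal(tab$ratio, tab$i_limit_model_a / tab$i_limit_shannon_a)
  # a low-impedance parameterization puts the model limit above Shannon's
  lim_hi <- safety_limits(-0.6, alpha_coeff = 1e-4, d1_exp = 1.0)
  tab_hi <- compare_to_shannon(m, lim_hi, 200e-6, 200e-6)
  expect_gt(tab_hi$ratio, 1)
})

test_that("check_pulse flags charge thresholds exactly at their limits", {
  lim <- safety_limits(-0.6)
  # micro contact at exactly 4 nC per phase: 20 uA x 200 us
  micro <- check_pulse(electrode_geometry(30e-6, contact_class = "micro"),
                       pulse_waveform(-20e-6, 200e-6), lim)
  expect_equal(micro$charge_per_phase_c, 4e-9)
  expect_equal(micro$checks$charge_per_phase$status, "at_limit")
  expect_match(micro$notices, "charge-only")

  # macro disc at exactly 30 uC/cm^2
  d_macro <- 2.3e-3
  area <- pi * (d_macro * 100)^2 / 4
  q_target <- 30e-6 * area
  t_pw <- 1e-3
  macro <- check_pulse(electrode_geometry(d_macro, contact_class = "macro"),
                       pulse_waveform(-q_target / t_pw, t_pw), lim)
  expect_equal(macro$charge_density_c_cm2, 30e-6, tolerance = 1e-12)
  expect_equal(macro$checks$charge_density$status, "at_limit")

  # comfortable pass and clear fail on either side
  expect_equal(check_pulse(electrode_geometry(30e-6, contact_class = "micro"),
                           pulse_waveform(-10e-6, 200e-6), lim)$status, "pass")
  expect_equal(check_pulse(electrode_geometry(30e-6, contact_class = "micro"),
                           pulse_waveform(-40e-6, 200e-6), lim)$status, "fail")
})

test_that("check_pulse with a model also tests the excursion against E_mc", {
  m <- ref_excursion_model()
  lim <- safety_limits(-0.6)
  geom <- electrode_geometry(30e-6, contact_class = "micro")
  wave <- pulse_waveform(-10e-6, 200e-6)
  rep <- check_pulse(geom, wave, lim, model = m, z_imag_mag = 30)
  v_expect <- predict_excursion(m, 10, 200, 30)
  expect_equal(rep$checks$excursion$predicted_v, v_expect)
  expect_equal(rep$checks$excursion$status,
               if (v_expect < 0.6) "pass" else "fail")
  expect_length(rep$notices, 0)
  expect_error(check_pulse(geom, wave, lim, model = m), "z_imag_mag")
})

test_that("zero-amplitude pulses consume no safety margin", {
  lim <- safety_limits(-0.6)
  wave <- pulse_waveform(-0, 200e-6)
  rep <- check_pulse(electrode_geometry(30e-6, contact_class = "micro"),
                     wave, lim)
  expect_equal(rep$charge_per_phase_c, 0)
  expect_equal(rep$status, "pass")
})

test_that("geometry and limits validate their invariants", {
  expect_error(electrode_geometry(-1e-4), "diameter")
  expect_error(electrode_geometry(1e-4, separation = 5e-5), "separation")
  expect_error(safety_limits(0), "e_mc")
  expect_error(safety_limits(-0.6, alpha_coeff = -2), "alpha_coeff")
  # positive e_mc is stored negated (cathodal convention)
  expect_equal(safety_limits(0.6)$e_mc, -0.6)
})
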