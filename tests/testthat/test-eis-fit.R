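test_that("a noise-free spectrum is recovered to 0.1% from a x2-perturbed start", {
  truth <- ref_circuit()
  spec <- gen_eis(truth, 0.1, 1e5, 40, noise_spec(sigma = 0))
  fit <- fit_interface(spec, ref_circuit_init(), seed = 1)
  expect_true(fit$converged)
  err <- abs(circuit_param_vec(fit$circuit) / circuit_param_vec(truth) - 1)
  expect_lt(max(err), 1e-3)
})

test_that("fits are deterministic given the seed and improve on the initial guess", {
  truth <- ref_circuit()
  spec <- gen_eis(truth, 0.1, 1e5, 40,
                  noise_spec("multiplicative_complex_gaussian", 0.02,
                             seed = 42))
  f1 <- fit_interface(spec, ref_circuit_init(), seed = 7)
  f2 <- fit_interface(spec, ref_circuit_init(), seed = 7)
  expect_identical(f1$estimates$value, f2$estimates$value)
  expect_gte(f1$residual_norm, 0)
  # residual at the solution <= residual at the initial guess
  resid_at <- function(circ) {
    zh <- interface_impedance(circ, spec$freq_hz)$z_ohm
    w <- 1 / Mod(spec$z_ohm)
    sqrt(sum((c(Re(zh - spec$z_ohm), Im(zh - spec$z_ohm)) * c(w, w))^2))
  }
  expect_lte(f1$residual_norm, resid_at(ref_circuit_init()))
})

test_that("a pure resistor spectrum drives the CPE branches to irrelevance", {
  freqs <- 10^seq(-1, 5, length.out = 40)
  spec <- impedance_spectrum(freqs, rep(8e3 + 0i, 40))
  fit <- fit_interface(spec, ref_circuit_init(), seed = 3)
  zfit <- interface_impedance(fit$circuit, freqs)$z_ohm
  # fitted |Z| matches the flat input at every point
  expect_equal(Mod(zfit), rep(8e3, 40), tolerance = 0.01)
})

test_that("fitting is invariant to a global impedance rescale", {
  truth <- ref_circuit()
  spec <- gen_eis(truth, 0.1, 1e5, 40,
                  noise_spec("multiplicative_complex_gaussian", 0.02,
                             seed = 5))
  spec10 <- impedance_spectrum(spec$freq_hz, spec$z_ohm * 10)
  init <- ref_circuit_init()
  init10 <- interface_circuit(
    c_dl = cpe_params(init$c_dl$q_coeff / 10, init$c_dl$n_exp),
    r_ct = init$r_ct * 10,
    c_f = cpe_params(init$c_f$q_coeff / 10, init$c_f$n_exp),
    r_spread = init$r_spread * 10, r_bulk = init$r_bulk * 10
  )
  f <- fit_interface(spec, init, seed = 2)
  f10 <- fit_interface(spec10, init10, seed = 2)
  p <- circuit_param_vec(f$circuit)
  p10 <- circuit_param_vec(f10$circuit)
  scale <- c(q_dl = 0.1, n_dl = 1, r_ct = 10, q_f = 0.1, n_f = 1,
             r_series = 10)
  expect_equal(p10, p * scale, tolerance = 1e-5)
})

test_that("degenerate spectra and bad inits are rejected", {
  truth <- ref_circuit()
  narrow <- gen_eis(truth, 100, 900, 10, noise_spec(sigma = 0))
  expect_error(fit_interface(narrow, ref_circuit_init()), "2 decades")
  small <- gen_eis(truth, 0.1, 1e5, 5, noise_spec(sigma = 0))
  expect_error(fit_interface(small, ref_circuit_init()), "8 frequency")
})

test_that("diameter power law is recovered exactly from exact data", {
  d <- c(20, 50, 100, 200, 500) * 1e-6
  z <- 3e-3 * d^(-2)
  sc <- fit_diameter_scaling(d, z)
  expect_equal(sc$d1_exp, 2, tolerance = 1e-12)
  expect_equal(sc$alpha_coeff, 3e-3, tolerance = 1e-9)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
})

test_that("diameter exponent survives 5% lognormal noise within 10%", {
  set.seed(7)
  d <- 10^seq(log10(20e-6), log10(2e-3), length.out = 12)
  z_true <- 5e-2 * d^(-1.4)
  z <- z_true * exp(0.05 * rnorm(length(d)))
  sc <- fit_diameter_scaling(d, z)
  expect_equal(sc$d1_exp, 1.4, tolerance = 0.1)
})

test_that("degenerate diameter designs are rejected", {
  expect_error(fit_diameter_scaling(rep(1e-4, 5), runif(5, 1, 2) * 1e3),
               "distinct")
  expect_error(fit_diameter_scaling(c(1e-4, 2e-4), c(1e3, 2e3)), "distinct")
  expect_error(fit_diameter_scaling(c(1e-4, 2e-4, -3e-4), c(1, 2, 3)),
               "positive")
})
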