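fe_negligible_caps <- function(r_in = 16e6) {
  recording_front_end(r_in = r_in, c_in = 1e-15, c_parasitic = 1e-15)
}

test_that("coupling coefficient behaves as a voltage divider", {
  fe <- fe_negligible_caps()
  # zero electrode impedance couples perfectly
  expect_equal(coupling_coefficient(0, fe, 1000), 1)
  # equal resistive divider halves the signal
  expect_equal(coupling_coefficient(16e6, fe, 1000), 0.5, tolerance = 1e-3)
  # Ti-like 1.5 Mohm against a 16 Mohm input: 16/17.5
  cc_ti <- coupling_coefficient(1.5e6, fe, 1000)
  expect_equal(cc_ti, 16 / 17.5, tolerance = 1e-3)
  expect_equal(cc_ti, 0.914, tolerance = 1e-3)
  # monotone decreasing in |z| at fixed phase
  cc <- coupling_coefficient(c(1e4, 1e5, 1e6, 1e7), fe, 1000)
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc > 0 & cc <= 1))
})

test_that("electrode-to-input impedance ratio reproduces the Ti figure", {
  expect_equal(impedance_ratio(1.5e6, 16e6), 9.375)
  expect_lte(impedance_ratio(1.5e6, 16e6), 10)
})

test_that("material presets order coupling as PEDOT > Pt > Ti at 1 kHz", {
  p <- material_presets()
  fe <- recording_front_end()
  cc <- vapply(p[c("PEDOT_PSS", "Pt_planar", "Ti")], function(circ) {
    z <- interface_impedance(circ, 1000)$z_ohm
    coupling_coefficient(z, fe, 1000)
  }, numeric(1))
  expect_true(cc[["PEDOT_PSS"]] > cc[["Pt_planar"]])
  expect_true(cc[["Pt_planar"]] > cc[["Ti"]])
})

test_that("thermal noise follows the Johnson-Nyquist closed form", {
  # flat 400 kohm over 10 kHz at 300 K: ~8.14 uV
  v <- thermal_noise_rms(c(0, 10e3), 400e3, 300)
  expect_equal(v, sqrt(4 * 1.380649e-23 * 300 * 4e5 * 1e4), tolerance = 1e-12)
  expect_equal(v * 1e6, 8.14, tolerance = 1e-3)
  # zero resistance is silent
  expect_equal(thermal_noise_rms(c(0, 10e3), 0), 0)
  # exact sqrt(R) and sqrt(B) scaling for flat spectra
  expect_equal(thermal_noise_rms(c(0, 1e4), 4 * 400e3), 2 * v)
  expect_equal(thermal_noise_rms(c(0, 4e4), 400e3), 2 * v)
  # frequency-dependent profile with equal integral gives identical rms
  freqs <- seq(0, 1e4, length.out = 101)
  ramp <- seq(0, 8e5, length.out = 101)  # mean 4e5 -> same integral
  expect_equal(thermal_noise_rms(freqs, ramp), v, tolerance = 1e-12)
  expect_error(thermal_noise_rms(freqs, ramp - 1e5), "non-physical")
})

test_that("conduction delay is separation over speed", {
  expect_equal(conduction_delay(50e-6, 1), 50e-6)
  expect_equal(conduction_delay(50e-6, 0.2), 250e-6)
  expect_error(conduction_delay(0, 1), "separation")
})

test_that("data rate is exact integer arithmetic with decimal Gbps", {
  r <- data_rate(n_channels = 4096, sample_rate = 30e3, bit_depth = 16)
  expect_identical(r$bits_per_s, 1966080000)
  expect_equal(r$gbps, 1.96608)
  expect_equal(data_rate(n_channels = 1, sample_rate = 1,
                         bit_depth = 1)$bits_per_s, 1)
  r2 <- data_rate(n_channels = 8192, sample_rate = 30e3, bit_depth = 16)
  expect_identical(r2$bits_per_s, 2 * r$bits_per_s)
  fe <- recording_front_end(n_channels = 4096, sample_rate = 30e3,
                            bit_depth = 16)
  expect_identical(data_rate(fe)$bits_per_s, r$bits_per_s)
  expect_error(data_rate(n_channels = 2.5, sample_rate = 1, bit_depth = 1),
               "integer")
})

test_that("crosstalk bound rises with impedance and capacitance", {
  expect_equal(crosstalk_bound(1e6, 0, 1000), 0)
  zc <- 1 / (2 * pi * 1000 * 1e-12)
  expect_equal(crosstalk_bound(zc, 1e-12, 1000), 0.5)
  # Ti (1.5 Mohm) strictly worse than PEDOT (30 kohm) at equal parasitics
  expect_gt(crosstalk_bound(1.5e6, 1e-12, 1000),
            crosstalk_bound(30e3, 1e-12, 1000))
  b <- crosstalk_bound(c(1e4, 1e5, 1e6), 1e-12, 1000)
  expect_true(all(diff(b) > 0))
})

test_that("front-end validation warns on sub-Nyquist sampling", {
  expect_warning(recording_front_end(bandwidth = 20e3, sample_rate = 30e3),
                 "Nyquist")
  expect_error(recording_front_end(r_in = -1), "r_in")
})
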