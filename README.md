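# electrode

Modeling the electrochemical interface of neural recording and stimulation
contacts, and the safety and signal budgets that follow from it.

Clinical and research brain interfaces — ECoG grids, sEEG depth leads,
penetrating microelectrode arrays — couple to tissue through an
electrochemical interface whose impedance governs both directions of use.
Scaling contacts down for spatial resolution raises that impedance, which
attenuates and delays recorded signals, adds thermal noise, and lowers the
current that can be injected before the interface potential crosses the
water-electrolysis window.  `electrode` is an R package for engineers and
electrophysiologists who need to quantify those trade-offs for disc
contacts from tens of micrometers to millimeters.

## What it computes

**Interface circuit.**  The electrode–tissue interface as a
constant-phase-element (CPE) network,

    Z(f) = R_bulk + R_spread + [ Z_CDL || (R_CT + Z_CF) ],

with CPE impedance `Z = 1/(Q (jω)^n)`, disc spreading resistance
`ρ/(2D)`, frequency sweeps (`interface_impedance`), and current-clamped
pulse transients via a Grünwald–Letnikov fractional-order integrator
(`pulse_transient`, `excursion_extrema`).

**EIS fitting.**  Complex nonlinear least squares of the circuit to
measured or synthetic spectra with modulus weighting and seeded multistart
(`fit_interface`), and the diameter power law `|Z_imag| = α D^(−d1)`
(`fit_diameter_scaling`).

**Stimulation safety.**  The empirical excursion-potential model

    V_elec = a · ln( b · |I|^k2 · t_pw^k4 · |Z_imag|^k6 + 1 ),

its fit from excursion datasets (`fit_excursion_model`), the closed-form
current-injection limit at the cathodal electrolysis potential E_mc, its
diameter-scaled form

    |I_limit| = [ α' D^(−d1·k6) / (b · t_pw^k4) · (e^{|E_mc|/a} − 1) ]^(1/k2),

Shannon's equation `I = (D / 2 t_pw) · sqrt(π · 10^k)` for comparison
(`compare_to_shannon`), and pulse checking against the empirical safety
thresholds of 30 µC/cm² (macro-contacts) and 4 nC per phase
(micro-contacts) (`check_pulse`).

**Recording budgets.**  Coupling coefficient
`CC = |Z_shunt| / |Z_shunt + Z_elec|`, Johnson–Nyquist thermal noise,
conduction delay, capacitive crosstalk bounds, and acquisition data rate.

**Synthetic data.**  Seeded generators for noisy EIS spectra and excursion
datasets (`gen_eis`, `gen_excursion_dataset`) plus material presets (Ti,
planar Pt, PEDOT:PSS, PtNR) calibrated to measured 1 kHz impedance
magnitudes (`material_presets`).

## Worked example

```r
library(electrode)

# Material presets, calibrated to their 1 kHz anchors
p <- material_presets()
sapply(p, function(c) Mod(interface_impedance(c, 1000)$z_ohm))
#>        Ti Pt_planar PEDOT_PSS      PtNR
#>   1500000    400000     30000     25000

# Ti couples noticeably worse into a 16 Mohm amplifier input
fe <- recording_front_end(r_in = 16e6)
sapply(p, function(c)
  coupling_coefficient(interface_impedance(c, 1000)$z_ohm, fe, 1000))
#>        Ti Pt_planar PEDOT_PSS      PtNR
#> 0.9713230 0.9929459 0.9996286 0.9996907

impedance_ratio(1.5e6, 16e6)   # Ti reaches 9.375% of the amplifier input
thermal_noise_rms(c(0, 10e3), 400e3) * 1e6   # planar Pt: 8.14 uV rms

# Safety: a fitted excursion model vs Shannon's equation
m   <- excursion_model(0.5, 0.005, 1, 0.5, 0.5)   # units: uA, us, kohm
lim <- safety_limits(-0.6, alpha_coeff = 1e-4, d1_exp = 1.0)
compare_to_shannon(m, lim, diameters = 200e-6, t_pws = 200e-6)
#>   diameter_m t_pw_s i_limit_model_a i_limit_shannon_a    ratio
#> 1      2e-04  2e-04     0.001467371       0.000745667 1.967863

# Pulse check: 20 uA x 200 us on a 30 um micro-contact
rep <- check_pulse(electrode_geometry(30e-6, contact_class = "micro"),
                   pulse_waveform(-20e-6, 200e-6), lim,
                   model = m, z_imag_mag = 30)
rep
#> <safety_report> micro contact: overall FAIL
#>   charge/phase: 4 nC; density: 565.9 uC/cm^2
#>   charge_per_phase: at_limit
#>   excursion: fail
```

The pulse sits exactly at the 4 nC/phase charge threshold, and for this
(illustrative) excursion model the predicted interface potential also
exceeds the 0.6 V electrolysis limit, so the report fails the pulse.

A command-line interface covering the same operations is installed at
`inst/exec/electrode`:

```sh
Rscript inst/exec/electrode shannon --d 200um --t-pw 200us --k 1.85
Rscript inst/exec/electrode budget --channels 4096 --fs 30000 --bits 16
```

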