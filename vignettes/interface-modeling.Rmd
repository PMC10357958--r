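---
title: "Modeling the electrode-tissue interface: circuits, safety limits, and recording budgets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the electrode-tissue interface: circuits, safety limits, and recording budgets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(electrode)
```

## The problem

A neural electrode contact talks to tissue through an electrochemical
interface, and that interface — not the wire behind it — sets most of what
the contact can do.  On the recording side, its impedance divides against
the amplifier input and raises thermal noise; on the stimulation side, the
potential that builds up across it during a current pulse decides how much
charge can be injected before water electrolysis begins.  This package
provides the forward models, the fitting machinery and the safety
bookkeeping for both sides, for disc contacts from tens of micrometers
(micro-contacts) to millimeters (clinical macro-contacts).

## The equivalent circuit

The interface is modeled as

$$Z(f) = R_{bulk} + R_{spread} + \left[ Z_{C_{DL}} \,\|\, (R_{CT} + Z_{C_F}) \right],$$

with three ingredients:

* **Double-layer CPE** ($C_{DL}$).  The thin ionic screening layer at the
  contact behaves as a *constant-phase element*, a nonideal capacitor with
  $Z = 1/(Q (j\omega)^n)$, $0 < n \le 1$.  Its phase is $-n \cdot 90°$ at
  every frequency, and $n = 1$ recovers an ideal capacitor with $C = Q$.
  $Q$ carries units of S·s$^n$.
* **Faradaic branch** ($R_{CT}$ in series with a second CPE $C_F$).  Direct
  charge transfer across the interface plus the limited ion migration that
  can feed a redox reaction.  A purely capacitive contact is represented by
  an explicit infinite-$R_{CT}$ flag rather than a large number, which
  would otherwise poison the conditioning of fits and transients.
* **Access and bulk resistances.**  Current crowding at the disc perimeter
  gives the spreading resistance $R_{spread} = \rho/(2D)$ for a disc of
  diameter $D$ in a medium of resistivity $\rho$; $R_{bulk}$ covers
  conduction through the tissue volume.

The wiring of the faradaic CPE (in series with $R_{CT}$, inside the
parallel branch) is the standard Randles-style extension; the topology is
fixed, and model selection across topologies is deliberately out of scope.
Elements are linear and bias-independent; the drift of interface elements
with applied bias that real interfaces show is exposed only as
`bias_rescale_hook()`, an identity by default, so users with measured bias
dependence can inject it without the package inventing numbers.

```{r}
circ <- interface_circuit(
  c_dl = cpe_params(2e-7, 0.85), r_ct = 2e5,
  c_f = cpe_params(1e-6, 0.7), r_spread = 5e3, r_bulk = 1e3,
  label = "example microcontact"
)
spectrum_bode(interface_impedance(circ, c(10, 100, 1000, 10000)))
```

## Pulse transients by fractional calculus

A CPE's constitutive law is a fractional derivative,
$i(t) = Q \, d^n v/dt^n$, so the voltage under a current-clamped pulse is
not an exponential.  `pulse_transient()` integrates the circuit with a
Grünwald–Letnikov discretization: the fractional derivative becomes a
convolution over the full voltage history with binomial weights
$w_j = (-1)^j \binom{n}{j}$, leaving one small linear solve per timestep.
Design choices:

* **Timestep.**  Waveform construction enforces $dt \le t_{pw}/50$ so each
  phase is resolved; the default $dt = t_{pw}/1000$ reproduces the pure-CPE
  step-response closed form $V(t) = I t^n / (Q\,\Gamma(1+n))$ to better
  than 0.1% in the cases exercised by the tests (the documented
  convergence tolerance on excursion extrema is 0.5%).
* **Cost.**  The history convolution is $O(N^2)$; a sample-count ceiling
  (default $2 \times 10^6$) turns runaway requests into an error that
  advises a larger `dt` or a shorter waveform.
* **Consistency.**  For sinusoidal drive the steady-state amplitude and
  phase of the simulated voltage match `interface_impedance()` within 2%,
  which ties the time- and frequency-domain paths of the package together.
* **Start from rest.**  Simulations assume zero interface polarization at
  $t = 0$; charge accumulated across repeated unbalanced pulses is visible
  in the trace but no electrode "memory" beyond the simulated window is
  modeled.

## Fitting impedance spectra

`fit_interface()` performs complex nonlinear least squares on stacked
(Re, Im) residuals with Levenberg–Marquardt (`minpack.lm`).  Choices that
matter:

* **Weighting.**  Default *modulus* weighting (residuals divided by $|Z|$
  per point) keeps decade-spanning spectra from being dominated by their
  low-frequency tail.  `unit` and `proportional` weightings are available.
* **Positivity and bounds.**  Magnitude parameters are fitted in log
  space; CPE exponents are clipped to $[0.3, 1]$ during fitting to keep
  the fit away from Warburg-like degeneracy.  Both are overridable.
* **Multistart.**  Five seeded starts (the initial guess plus four
  log-uniform perturbations in ×1/3…×3); the lowest weighted residual
  wins, ties broken by iteration count then lexicographic parameter order.
  Given the seed, the fit is fully deterministic.
* **Identifiability.**  $R_{spread}$ and $R_{bulk}$ enter $Z(f)$ only
  through their sum, so a single series resistance is estimated and split
  back in the proportion of the initial guess.  Recovery claims are made
  for the sum, which is what the data constrain.

`fit_diameter_scaling()` fits $|Z_{imag}| = \alpha D^{-d_1}$ as a line in
log–log space (at a 1 kHz reference frequency by default, the usual
reporting frequency); $\alpha$ and $d_1$ feed the diameter-scaled current
limit below.

## Stimulation safety

The excursion potential under a pulse of current $I$, width $t_{pw}$,
against an interface with imaginary impedance magnitude $|Z_{imag}|$ is
modeled empirically as

$$V_{elec} = a \ln\!\big( b\, |I|^{k_2}\, t_{pw}^{k_4}\, |Z_{imag}|^{k_6} + 1 \big),$$

which is zero at zero current, quasi-linear for small arguments and
saturating for large ones.  Setting $V_{elec}$ equal to the cathodal
electrolysis limit $|E_{mc}|$ (from cyclic voltammetry, supplied by the
user — CV is not simulated here) and inverting gives the current limit,
and substituting the diameter power law gives

$$|I_{limit}| = \left[ \frac{\alpha' D^{-d_1 k_6}}{b\, t_{pw}^{k_4}}
  \left( e^{|E_{mc}|/a} - 1 \right) \right]^{1/k_2}.$$

The two forms are algebraically identical and the package verifies the
round trip to $10^{-10}$ relative.  For comparison, Shannon's relation
$\log(Q/A) = k - \log Q$ for a disc of diameter $D$ yields
$I_{limit} = \frac{D}{2 t_{pw}} \sqrt{\pi\, 10^k}$ ($Q$ in µC with $D$ in
cm); the typeset form of this equation is ambiguous in places, and the
$D/(2 t_{pw})$ rendering is the one consistent with the charge-density
derivation, which the tests check independently by solving
$\log_{10}(Q/A) = k - \log_{10} Q$ numerically.

**Units.**  Because $b$ is unit-dependent, every `excursion_model` carries
a mandatory declaration of the units its parameters were fitted in
(default µA, µs, kΩ — the natural scales of benchtop sweeps).  Model
evaluations take their inputs in the declared units; passing a conflicting
declaration is an error, never a silent conversion.  `convert_unit()` and
the CLI's suffixed quantities (`200us`, `30kohm`) do explicit conversions
at the boundaries, and `compare_to_shannon()` reports everything in
amperes.

**Sign conventions.**  $E_{mc}$ is stored signed (negative cathodal);
comparisons use magnitudes.  Pulses are cathodic-first, amplitude negative.

**Fitting.**  `fit_excursion_model()` mirrors the EIS fitter: all five
parameters in log space (they are all positive), seeded 5-way multistart,
deterministic given the seed.  The design must span at least a decade in
both current and pulse width with at least 20 points: with a narrower
design, $a$ and $b$ decouple only weakly through the curvature of
$\ln(1+x)$ and the fit is effectively rank-deficient.

**Thresholds.**  `check_pulse()` computes charge per phase
$|I| \cdot t_{pw}$ and geometric charge density over the disc area
$\pi D^2/4$, and flags micro-contacts against 4 nC per phase and
macro-contacts against 30 µC/cm², the empirical safety limits in common
clinical use.  A quantity within $10^{-6}$ relative of its threshold is
reported `at_limit` rather than forced to either side.  Inter-contact
separation is carried as geometry metadata but has no quantitative effect
on limits: no published separation model is available, so none is
invented.  Chronic sub-electrolysis damage mechanisms are likewise out of
scope.

```{r}
m <- excursion_model(0.5, 0.005, 1, 0.5, 0.5)
lim <- safety_limits(-0.6, alpha_coeff = 1e-4, d1_exp = 1.0)
compare_to_shannon(m, lim, diameters = 200e-6, t_pws = 200e-6)
```

## Recording side

The recorded amplitude relative to the signal at the electrode surface is
the *coupling coefficient*,
$CC = |Z_{shunt}| / |Z_{shunt} + Z_{elec}|$ with
$Z_{shunt} = R_{in} \| 1/(j\omega(C_{in} + C_{par}))$: one lumped divider
for the amplifier input and parasitic shunt, which is as much structure as
qualitative attenuation measurements support.  Thermal noise integrates
the Johnson–Nyquist density over the band,
$v_{rms} = \sqrt{4 k_B T \int \mathrm{Re}\,Z(f)\, df}$ (trapezoidal rule);
flicker (1/f) noise has no accepted parameter-free model and is therefore
not added silently — the interface accepts only what the user measures.
`conduction_delay()`, `crosstalk_bound()` and `data_rate()` (exact integer
arithmetic, decimal-prefix Gbps) complete the acquisition budget.

## Synthetic data and the material presets

All tests run on synthetic data, because the generators are exact inverses
of the fitters' forward models at zero noise:

* `gen_eis()` evaluates a known circuit on a log grid and applies
  multiplicative complex Gaussian noise (2% in the recovery studies —
  a typical benchtop EIS repeatability), additive, or lognormal noise.
* `gen_excursion_dataset()` evaluates a known excursion model on a full
  factorial grid and adds 5 mV Gaussian noise to the voltages in the
  recovery studies — the scale of oscilloscope reads of excursion
  potentials.  The reference design is 5 currents × 4 pulse widths × 3
  impedances (60 points) spanning 10–200 µA, 50–500 µs and 10–100 kΩ.
* Every generator is seeded; a single global seed fans out to stream
  seeds via `child_seed()` so pipelines are reproducible end to end.

`material_presets()` ships circuits for Ti, planar Pt, PEDOT:PSS and PtNR
contacts calibrated so that their modeled 1 kHz magnitudes match the
measured anchors (1.5 MΩ, 400 kΩ, 30 kΩ).  The calibration fixes the CPE
exponent per material (0.90 for the metals, 0.95 for the coatings —
plausible, not measured), puts 10% of the target into series resistance
(split evenly), and solves the CPE coefficient by root finding.  The PtNR
target (25 kΩ) is itself a plausible synthetic choice, not a printed
measurement.  Only the three 1 kHz anchors are empirical; everything else
about the presets is a documented modeling choice, so conclusions drawn
from preset *spectral shapes* (as opposed to 1 kHz magnitudes and their
ordering) should be treated accordingly.

What passing the synthetic recovery studies shows is that the estimators
are consistent and well-conditioned under the stated noise; it does not
show that real tissue interfaces obey a two-branch CPE circuit or the
five-parameter excursion law exactly — nonlinearity, drift and bias
dependence of real interfaces are precisely what the linearized model
assumes away.

## Problem sizes and numerical choices

The recovery studies use 40-point spectra (0.1 Hz–100 kHz) with 20
replicate noise draws, 60-point excursion grids, and 1000-step transients
— sizes at which every study in the test suite completes in seconds while
leaving the asymptotics visible.  Tolerances used throughout: 0.1% for
zero-noise identifiability, 0.5% for transient convergence, $10^{-10}$
relative for algebraic identities, 2% for transient/spectral consistency.
Degenerate inputs (single-decade spectra, single-valued designs, equal
diameters, empty grids, negative resistances) are rejected with named
errors rather than patched.

## Known limitations

* Single fixed circuit topology; no Warburg element, no reaction kinetics,
  no temperature dependence.
* The excursion model is empirical; its parameters are setup-specific and
  must be refitted per electrode family and medium.
* $|Z_{imag}|$ enters the safety model at a fixed reference frequency
  (1 kHz by default) rather than a pulse-matched frequency; this is a
  documented convention, configurable at the call sites.
* The transient integrator is first-order accurate; error scales with
  $n \cdot dt / t$, which is ample for excursion extrema but not intended
  for high-order spectral analysis of the traces.
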