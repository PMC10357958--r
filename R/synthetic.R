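#' Noise specification for synthetic generators
#'
#' @param kind `"multiplicative_complex_gaussian"` (relative sigma applied
#'   independently to the real and imaginary parts of `Z * (1 + s(e_r +
#'   i e_i))`), `"additive_gaussian"` (absolute sigma in the output's
#'   units), or `"lognormal"` (multiplicative `exp(s e)` factor).
#' @param sigma Noise scale, >= 0 (relative for multiplicative kinds,
#'   absolute for additive).
#' @param seed Integer seed; identical spec + seed reproduce the output
#'   bit for bit.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("multiplicative_complex_gaussian",
                                "additive_gaussian", "lognormal"),
                       sigma = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0) {
    stop("`sigma` must be a single number >= 0", call. = FALSE)
  }
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Derive a child seed from a global seed
#'
#' Generators fan a single global seed out to per-stream child seeds with
#' `(seed + 1000003 * stream) mod (2^31 - 1)`, keeping streams decoupled
#' while the whole pipeline stays reproducible from one integer.
#'
#' @param seed Global integer seed.
#' @param stream Nonnegative stream index.
#' @return Integer child seed.
#' @export
child_seed <- function(seed, stream = 0L) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %%
               (2^31 - 1))
}

#' Generate a noisy impedance spectrum from a known circuit
#'
#' Evaluates the circuit on a log-spaced frequency grid and applies the
#' requested noise.  With `sigma = 0` the output equals
#' [interface_impedance()] exactly.
#'
#' @param circ An [interface_circuit].
#' @param f_lo,f_hi Frequency range, Hz; `f_lo < f_hi`.
#' @param n_points Number of log-spaced points, >= 2.
#' @param noise A [noise_spec].
#' @return An [impedance_spectrum]; its `meta` records the noise spec.
#' @export
gen_eis <- function(circ, f_lo = 0.1, f_hi = 1e5, n_points = 40L,
                    noise = noise_spec(sigma = 0)) {
  stopifnot(inherits(circ, "interface_circuit"),
            inherits(noise, "noise_spec"))
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_lo >= f_hi) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  if (n_points < 2L) stop("`n_points` must be >= 2", call. = FALSE)
  freqs <- 10^seq(log10(f_lo), log10(f_hi), length.out = n_points)
  z <- interface_impedance(circ, freqs)$z_ohm
  if (noise$sigma > 0) {
    set.seed(noise$seed)
    n <- length(z)
    z <- switch(noise$kind,
      multiplicative_complex_gaussian =
        z * (1 + noise$sigma * stats::rnorm(n) +
               1i * noise$sigma * stats::rnorm(n)),
      additive_gaussian =
        z + noise$sigma * stats::rnorm(n) +
          1i * noise$sigma * stats::rnorm(n),
      lognormal = z * exp(noise$sigma * stats::rnorm(n))
    )
  }
  impedance_spectrum(freqs, z,
                     meta = list(label = circ$label, synthetic = TRUE,
                                 noise_kind = noise$kind,
                                 noise_sigma = noise$sigma,
                                 noise_seed = noise$seed))
}

#' Generate a noisy excursion dataset from a known model
#'
#' Builds the full factorial grid of currents, pulse widths and impedance
#' values (in the model's declared units), evaluates the excursion model,
#' and adds noise to the voltages.  Generating parameters are recorded in
#' the dataset metadata.
#'
#' @param model An [excursion_model] (the generating truth).
#' @param i_grid Currents, declared current unit.
#' @param t_grid Pulse widths, declared time unit.
#' @param z_values Imaginary impedance magnitudes, declared impedance unit.
#' @param noise A [noise_spec]; `additive_gaussian` sigma is in volts.
#' @return An [excursion_dataset] with `length(i_grid) * length(t_grid) *
#'   length(z_values)` rows.
#' @export
gen_excursion_dataset <- function(model, i_grid, t_grid, z_values,
                                  noise = noise_spec("additive_gaussian",
                                                     sigma = 0)) {
  stopifnot(inherits(model, "excursion_model"),
            inherits(noise, "noise_spec"))
  if (length(i_grid) == 0L || length(t_grid) == 0L ||
      length(z_values) == 0L) {
    stop("grids must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(i_inj = i_grid, t_pw = t_grid, z_imag = z_values,
                      KEEP.OUT.ATTRS = FALSE)
  v <- predict_excursion(model, grid$i_inj, grid$t_pw, grid$z_imag)
  if (noise$sigma > 0) {
    set.seed(noise$seed)
    n <- length(v)
    v <- switch(noise$kind,
      additive_gaussian = v + noise$sigma * stats::rnorm(n),
      multiplicative_complex_gaussian =
        v * (1 + noise$sigma * stats::rnorm(n)),
      lognormal = v * exp(noise$sigma * stats::rnorm(n))
    )
    v <- pmax(v, 0)  # excursion magnitudes cannot be negative
  }
  excursion_dataset(grid$i_inj, grid$t_pw, grid$z_imag, v,
                    units_decl = model$units_decl,
                    meta = list(synthetic = TRUE,
                                generator = unclass(model),
                                noise_kind = noise$kind,
                                noise_sigma = noise$sigma,
                                noise_seed = noise$seed))
}

# Solve the CPE coefficient so that |Rs + Z_cpe(1 kHz)| hits a target.
calibrate_preset <- function(target_ohm, n_exp, series_frac = 0.1,
                             freq = 1000) {
  rs <- series_frac * target_ohm
  w <- 2 * pi * freq
  f_obj <- function(lq) {
    zc <- 1 / (exp(lq) * (1i * w)^n_exp)
    Mod(rs + zc) - target_ohm
  }
  lq <- stats::uniroot(f_obj, lower = -60, upper = 10,
                       tol = .Machine$double.eps^0.75)$root
  interface_circuit(
    c_dl = cpe_params(exp(lq), n_exp), r_ct = Inf,
    r_spread = rs / 2, r_bulk = rs / 2
  )
}

#' Packaged electrode material presets
#'
#' Interface-circuit presets for the contact materials compared at 1 kHz:
#' titanium (1.5 Mohm), planar platinum (400 kohm), PEDOT:PSS (30 kohm),
#' and platinum nanorods.  Each preset is calibrated deterministically:
#' the CPE exponent is fixed per material (Ti 0.9, Pt 0.9, PEDOT:PSS 0.95,
#' PtNR 0.95), the series resistance is set to 10 percent of the 1 kHz
#' target (split evenly between spreading and bulk), and the CPE
#' coefficient is solved so the modeled `|Z(1 kHz)|` matches the target
#' within 1 percent (in practice to numerical precision).  Only the 1 kHz
#' magnitudes of Ti, Pt and PEDOT:PSS are measured anchors; the CPE
#' exponents, the series split and the PtNR target (25 kohm) are plausible
#' synthetic choices.
#'
#' @return Named list of [interface_circuit] objects:
#'   `Ti`, `Pt_planar`, `PEDOT_PSS`, `PtNR`.
#' @examples
#' p <- material_presets()
#' Mod(interface_impedance(p$PEDOT_PSS, 1000)$z_ohm)  # ~30 kohm
#' @export
material_presets <- function() {
  spec <- list(
    Ti = list(target = 1.5e6, n = 0.90),
    Pt_planar = list(target = 400e3, n = 0.90),
    PEDOT_PSS = list(target = 30e3, n = 0.95),
    PtNR = list(target = 25e3, n = 0.95)
  )
  out <- lapply(names(spec), function(nm) {
    s <- spec[[nm]]
    circ <- calibrate_preset(s$target, s$n)
    circ$label <- sprintf("%s preset (|Z| = %g ohm at 1 kHz)", nm, s$target)
    circ
  })
  names(out) <- names(spec)
  out
}
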