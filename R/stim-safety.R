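#' Empirical excursion-potential model
#'
#' The interface potential that builds up during a current-clamped pulse is
#' modeled as
#' \deqn{V_{elec} = a \, \ln\!\left(b \, |I_{inj}|^{k_2} \, t_{pw}^{k_4} \,
#'   |Z_{imag}|^{k_6} + 1\right),}
#' with five empirical parameters that absorb the electrode design, the
#' material, the surrounding medium and setup variability.  Because `b` is
#' unit-dependent, the unit convention in which the model was fitted is
#' mandatory metadata (`units_decl`); all model evaluations take their
#' inputs in those units and no silent conversion is performed.
#'
#' @param a_scale Voltage scale `a`, V; > 0.
#' @param b_coeff Dimensionless coefficient `b` on the declared unit
#'   convention; > 0.
#' @param k2_exp,k4_exp,k6_exp Positive exponents of current, pulse width
#'   and imaginary impedance.
#' @param units_decl Named character vector declaring the units of `i`
#'   (current), `t` (pulse width) and `z` (imaginary impedance magnitude)
#'   used during fitting.  Default `c(i = "uA", t = "us", z = "kohm")`.
#'
#' @return An object of class `excursion_model`.
#' @examples
#' m <- excursion_model(0.5, 2, 1, 0.5, 0.5)
#' predict_excursion(m, i_inj = 1, t_pw = 1, z_imag_mag = 1)  # 0.5*log(3)
#' @export
excursion_model <- function(a_scale, b_coeff, k2_exp, k4_exp, k6_exp,
                            units_decl = c(i = "uA", t = "us", z = "kohm")) {
  vals <- c(a_scale = a_scale, b_coeff = b_coeff, k2_exp = k2_exp,
            k4_exp = k4_exp, k6_exp = k6_exp)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  units_decl <- validate_units_decl(units_decl)
  structure(
    list(a_scale = a_scale, b_coeff = b_coeff, k2_exp = k2_exp,
         k4_exp = k4_exp, k6_exp = k6_exp, units_decl = units_decl),
    class = "excursion_model"
  )
}

validate_units_decl <- function(units_decl) {
  if (is.null(names(units_decl)) ||
      !setequal(names(units_decl), c("i", "t", "z"))) {
    stop("`units_decl` must be a named vector with entries i, t, z",
         call. = FALSE)
  }
  ok <- list(i = c("A", "mA", "uA", "nA"),
             t = c("s", "ms", "us"),
             z = c("ohm", "kohm", "Mohm"))
  for (k in c("i", "t", "z")) {
    if (!units_decl[[k]] %in% ok[[k]]) {
      stop(sprintf("units_decl[%s] = `%s` is not a supported unit", k,
                   units_decl[[k]]), call. = FALSE)
    }
  }
  c(i = unname(units_decl[["i"]]), t = unname(units_decl[["t"]]),
    z = unname(units_decl[["z"]]))
}

#' @export
print.excursion_model <- function(x, ...) {
  cat(sprintf(
    "<excursion_model> V = %.4g * ln(%.4g * |I|^%.4g * t^%.4g * |Z|^%.4g + 1)\n",
    x$a_scale, x$b_coeff, x$k2_exp, x$k4_exp, x$k6_exp))
  cat(sprintf("  units: I in %s, t in %s, |Z_imag| in %s\n",
              x$units_decl[["i"]], x$units_decl[["t"]], x$units_decl[["z"]]))
  invisible(x)
}

check_model_units <- function(model, units) {
  if (!is.null(units)) {
    units <- validate_units_decl(units)
    if (!identical(units, model$units_decl)) {
      stop(sprintf(
        "unit convention mismatch: inputs declared (%s) but model fitted in (%s); no silent conversion is performed",
        paste(units, collapse = ","),
        paste(model$units_decl, collapse = ",")), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Predict the excursion potential
#'
#' Evaluates \eqn{V = a \ln(b |I|^{k_2} t^{k_4} |Z|^{k_6} + 1)}.  The
#' result is 0 exactly at zero current and strictly increasing in each of
#' `|I|`, `t_pw` and `|Z_imag|`.
#'
#' @param model An [excursion_model].
#' @param i_inj Injected current magnitude(s), in the model's declared
#'   current unit; >= 0.
#' @param t_pw Pulse width(s), declared time unit; > 0.
#' @param z_imag_mag Imaginary impedance magnitude(s), declared impedance
#'   unit; > 0 (conventionally taken at 1 kHz).
#' @param units Optional named units vector for the inputs; if supplied and
#'   different from the model's `units_decl`, an error is raised (no silent
#'   conversion).
#' @return Excursion potential magnitude(s), V.
#' @export
predict_excursion <- function(model, i_inj, t_pw, z_imag_mag, units = NULL) {
  stopifnot(inherits(model, "excursion_model"))
  check_model_units(model, units)
  if (any(!is.finite(i_inj)) || any(i_inj < 0)) {
    stop("`i_inj` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(t_pw)) || any(t_pw <= 0)) {
    stop("`t_pw` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(z_imag_mag)) || any(z_imag_mag <= 0)) {
    stop("`z_imag_mag` must be finite and > 0", call. = FALSE)
  }
  arg <- model$b_coeff * i_inj^model$k2_exp * t_pw^model$k4_exp *
    z_imag_mag^model$k6_exp
  model$a_scale * log1p(arg)
}

#' Current-injection limit from the excursion model
#'
#' Inverts the excursion model at the cathodal electrolysis limit:
#' \deqn{I_{limit} = \left[\frac{e^{|E_{mc}|/a} - 1}
#'   {b \, t_{pw}^{k_4} \, |Z_{imag}|^{k_6}}\right]^{1/k_2}.}
#' The inversion round-trips: `predict_excursion(model, I_limit, t, Z)`
#' returns `|e_mc|` to floating-point accuracy.
#'
#' @inheritParams predict_excursion
#' @param e_mc Cathodal electrolysis limit, V (signed, negative cathodal, or
#'   a magnitude; only `|e_mc|` is used and it must be nonzero).
#' @return Current limit(s) in the model's declared current unit.
#' @export
current_limit_from_model <- function(model, e_mc, t_pw, z_imag_mag,
                                     units = NULL) {
  stopifnot(inherits(model, "excursion_model"))
  check_model_units(model, units)
  if (!is.numeric(e_mc) || any(!is.finite(e_mc)) || any(e_mc == 0)) {
    stop("`e_mc` must be finite and nonzero (V)", call. = FALSE)
  }
  if (any(!is.finite(t_pw)) || any(t_pw <= 0)) {
    stop("`t_pw` must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(z_imag_mag)) || any(z_imag_mag <= 0)) {
    stop("`z_imag_mag` must be finite and > 0", call. = FALSE)
  }
  num <- expm1(abs(e_mc) / model$a_scale)
  den <- model$b_coeff * t_pw^model$k4_exp * z_imag_mag^model$k6_exp
  (num / den)^(1 / model$k2_exp)
}

#' Stimulation safety limits and scaling parameters
#'
#' Bundles the cathodal electrolysis limit, the diameter scaling of the
#' imaginary impedance, the Shannon coefficient, and the empirical charge
#' thresholds (30 uC/cm^2 for macro-contacts, 4 nC per phase for
#' micro-contacts).
#'
#' @param e_mc Cathodal electrolysis limit, V; stored signed (negative
#'   cathodal).  A positive value is stored negated.
#' @param alpha_coeff,d1_exp Diameter power-law parameters
#'   (\eqn{|Z_{imag}| = \alpha D^{-d_1}}, ohm at the reference frequency
#'   with D in m), e.g. from [fit_diameter_scaling()]; may be `NULL` until
#'   fitted.
#' @param shannon_k Shannon coefficient k (dimensionless), default 1.85.
#' @param q_density_macro Macro-contact charge-density threshold, uC/cm^2;
#'   default 30.
#' @param q_per_phase_micro Micro-contact charge-per-phase threshold, nC;
#'   default 4.
#' @param diameter_range Optional diameter range (m) over which the scaling
#'   was fitted; evaluations outside it warn.
#' @return An object of class `safety_limits`.
#' @export
safety_limits <- function(e_mc, alpha_coeff = NULL, d1_exp = NULL,
                          shannon_k = 1.85, q_density_macro = 30,
                          q_per_phase_micro = 4, diameter_range = NULL) {
  if (!is.numeric(e_mc) || length(e_mc) != 1L || !is.finite(e_mc) ||
      e_mc == 0) {
    stop("`e_mc` must be a single nonzero voltage (V)", call. = FALSE)
  }
  if (e_mc > 0) e_mc <- -e_mc
  if (q_density_macro <= 0 || q_per_phase_micro <= 0) {
    stop("charge thresholds must be strictly positive", call. = FALSE)
  }
  if (!is.null(alpha_coeff) &&
      (!is.finite(alpha_coeff) || alpha_coeff <= 0)) {
    stop("`alpha_coeff` must be positive and finite", call. = FALSE)
  }
  if (!is.null(d1_exp) && !is.finite(d1_exp)) {
    stop("`d1_exp` must be finite", call. = FALSE)
  }
  structure(
    list(e_mc = e_mc, alpha_coeff = alpha_coeff, d1_exp = d1_exp,
         shannon_k = shannon_k, q_density_macro = q_density_macro,
         q_per_phase_micro = q_per_phase_micro,
         diameter_range = diameter_range),
    class = "safety_limits"
  )
}

#' @export
print.safety_limits <- function(x, ...) {
  cat(sprintf("<safety_limits> E_mc = %.4g V (cathodal)\n", x$e_mc))
  if (!is.null(x$alpha_coeff)) {
    cat(sprintf("  |Z_imag|(D) = %.4g * D^-%.4g ohm (D in m)\n",
                x$alpha_coeff, x$d1_exp))
  }
  cat(sprintf(
    "  Shannon k = %.3g; thresholds: %.4g uC/cm^2 (macro), %.4g nC/ph (micro)\n",
    x$shannon_k, x$q_density_macro, x$q_per_phase_micro))
  invisible(x)
}

#' Diameter-scaled current-injection limit
#'
#' Combines the excursion-model inversion with the diameter power law
#' \eqn{|Z_{imag}| = \alpha D^{-d_1}} into
#' \deqn{|I_{limit}| = \left[\frac{\alpha' D^{-d_1 k_6}}{b \, t_{pw}^{k_4}}
#'   \left(e^{|E_{mc}|/a} - 1\right)\right]^{1/k_2},}
#' where \eqn{\alpha'} is the power-law prefactor converted to the model's
#' impedance unit and raised to \eqn{k_6}.  The result agrees with
#' [current_limit_from_model()] evaluated at
#' \eqn{|Z_{imag}| = \alpha D^{-d_1}} by construction.
#'
#' @param limits A [safety_limits] with `alpha_coeff`/`d1_exp` present
#'   (ohm-at-D-in-m convention, e.g. from [fit_diameter_scaling()]).
#' @param model An [excursion_model].
#' @param diameter Contact diameter(s), m.
#' @param t_pw Pulse width(s), in the model's declared time unit.
#' @return Current limit(s) in the model's declared current unit.
#' @export
current_limit_vs_diameter <- function(limits, model, diameter, t_pw) {
  stopifnot(inherits(limits, "safety_limits"),
            inherits(model, "excursion_model"))
  if (is.null(limits$alpha_coeff) || is.null(limits$d1_exp)) {
    stop(paste("`limits` has no diameter scaling; run fit_diameter_scaling()",
               "and store alpha_coeff/d1_exp first"), call. = FALSE)
  }
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("`diameter` must be positive and finite (m)", call. = FALSE)
  }
  if (!is.null(limits$diameter_range) &&
      (any(diameter < limits$diameter_range[1L]) ||
       any(diameter > limits$diameter_range[2L]))) {
    warning("diameter outside the fitted scaling range; extrapolating")
  }
  z_ohm <- limits$alpha_coeff * diameter^(-limits$d1_exp)
  z_model <- convert_unit(z_ohm, "ohm", model$units_decl[["z"]])
  current_limit_from_model(model, limits$e_mc, t_pw, z_model)
}

#' Shannon's equation current limit
#'
#' Shannon's relation \eqn{\log(Q/A) = k - \log Q} for a disc of diameter
#' \eqn{D} (area \eqn{\pi D^2/4}) gives a limiting charge per phase
#' \eqn{Q = (D/2)\sqrt{\pi \, 10^k}} (Q in uC when D is in cm), hence a
#' current limit
#' \deqn{I_{limit} = \frac{D}{2 t_{pw}} \sqrt{\pi \, 10^k}.}
#'
#' @param diameter Contact diameter, m.
#' @param t_pw Pulse width, s.
#' @param shannon_k Shannon coefficient, dimensionless (default 1.85).
#' @return Current limit, A.
#' @examples
#' shannon_limit(200e-6, 200e-6, 1.85)  # ~745.6 uA
#' @export
shannon_limit <- function(diameter, t_pw, shannon_k = 1.85) {
  if (any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("`diameter` must be positive and finite (m)", call. = FALSE)
  }
  if (any(!is.finite(t_pw)) || any(t_pw <= 0)) {
    stop("`t_pw` must be positive and finite (s)", call. = FALSE)
  }
  d_cm <- diameter * 100
  q_uc <- (d_cm / 2) * sqrt(pi * 10^shannon_k)
  i_ua <- q_uc / t_pw
  i_ua * 1e-6
}

#' Excursion dataset
#'
#' Rows of (injected current, pulse width, imaginary impedance magnitude,
#' measured cathodal excursion magnitude) in a declared unit convention.
#'
#' @param i_inj,t_pw,z_imag,v_elec Equal-length numeric vectors; currents
#'   etc. in `units_decl` units, `v_elec` the excursion magnitude in V.
#' @param units_decl Units of `i_inj`, `t_pw`, `z_imag` (see
#'   [excursion_model()]).
#' @param meta Named list of metadata (electrode label, medium, generating
#'   parameters for synthetic data).
#' @return A data frame of class `excursion_dataset` with attributes
#'   `units_decl` and `meta`.
#' @export
excursion_dataset <- function(i_inj, t_pw, z_imag, v_elec,
                              units_decl = c(i = "uA", t = "us", z = "kohm"),
                              meta = list()) {
  n <- length(i_inj)
  if (length(t_pw) != n || length(z_imag) != n || length(v_elec) != n) {
    stop("all columns must have the same length", call. = FALSE)
  }
  if (any(!is.finite(i_inj)) || any(i_inj <= 0) ||
      any(!is.finite(t_pw)) || any(t_pw <= 0) ||
      any(!is.finite(z_imag)) || any(z_imag <= 0)) {
    stop("i_inj, t_pw and z_imag must be positive and finite",
         call. = FALSE)
  }
  if (any(!is.finite(v_elec)) || any(v_elec < 0)) {
    stop("`v_elec` must be finite excursion magnitudes >= 0 (V)",
         call. = FALSE)
  }
  out <- data.frame(i_inj = i_inj, t_pw = t_pw, z_imag = z_imag,
                    v_elec = v_elec)
  attr(out, "units_decl") <- validate_units_decl(units_decl)
  attr(out, "meta") <- meta
  class(out) <- c("excursion_dataset", "data.frame")
  out
}

#' Fit the excursion-potential model to a dataset
#'
#' Nonlinear least squares on the excursion voltage, with all five
#' parameters fitted in log space to enforce positivity, a seeded 5-way
#' multistart (initial guess plus four log-uniform ×1/3 ... ×3
#' perturbations), and ties broken by residual then lexicographic parameter
#' order.  Requires at least 20 rows spanning at least one decade in both
#' current and pulse width (a single-valued current or pulse-width design
#' is rank-deficient for the exponents).
#'
#' @param data An [excursion_dataset].
#' @param init An [excursion_model] initial guess; its `units_decl` must
#'   match the dataset's.
#' @param seed Integer seed for the multistart jitter.
#' @param n_starts Number of multistart points.
#' @return List of class `excursion_fit`: `model` (fitted
#'   [excursion_model]), `rmse` (V), `estimates` (values with approximate
#'   standard errors), `converged`, `n_iter`, `seed`.
#' @export
fit_excursion_model <- function(data, init, seed = 1L, n_starts = 5L) {
  stopifnot(inherits(data, "excursion_dataset"),
            inherits(init, "excursion_model"))
  if (!identical(attr(data, "units_decl"), init$units_decl)) {
    stop("dataset and init unit conventions differ; convert explicitly",
         call. = FALSE)
  }
  if (nrow(data) < 20L) {
    stop("need at least 20 rows", call. = FALSE)
  }
  for (col in c("i_inj", "t_pw")) {
    v <- data[[col]]
    if (length(unique(v)) < 2L) {
      stop(sprintf("rank-deficient design: `%s` takes a single value", col),
           call. = FALSE)
    }
    if (max(v) / min(v) < 10) {
      stop(sprintf("`%s` must span at least one decade", col),
           call. = FALSE)
    }
  }
  nm <- c("a_scale", "b_coeff", "k2_exp", "k4_exp", "k6_exp")
  th0 <- log(unlist(init[nm]))
  li <- log(data$i_inj); lt <- log(data$t_pw); lz <- log(data$z_imag)
  resid_fn <- function(th) {
    p <- exp(th)
    arg <- exp(log(p[2L]) + p[3L] * li + p[4L] * lt + p[5L] * lz)
    data$v_elec - p[1L] * log1p(arg)
  }
  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  starts[[1L]] <- th0
  for (s in seq_len(n_starts - 1L)) {
    starts[[s + 1L]] <- th0 + stats::runif(length(th0), -log(3), log(3))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 1000)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    if (is.null(best) || rn < best$rn ||
        (rn == best$rn &&
         paste(fit$par, collapse = ",") <
           paste(best$fit$par, collapse = ","))) {
      best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best)) stop("all multistart fits failed", call. = FALSE)
  fit <- best$fit
  p <- exp(as.numeric(fit$par))
  se <- rep(NA_real_, 5L)
  if (!is.null(fit$hessian)) {
    dof <- max(length(fit$fvec) - 5L, 1L)
    s2 <- sum(fit$fvec^2) / dof
    cv <- try(solve(fit$hessian) * s2, silent = TRUE)
    if (!inherits(cv, "try-error")) se <- sqrt(pmax(diag(cv), 0)) * p
  }
  model <- excursion_model(p[1L], p[2L], p[3L], p[4L], p[5L],
                           units_decl = init$units_decl)
  structure(
    list(model = model,
         rmse = sqrt(mean(fit$fvec^2)),
         estimates = data.frame(param = nm, value = p, se = se),
         converged = fit$info %in% 1:4,
         n_iter = fit$niter,
         seed = as.integer(seed)),
    class = "excursion_fit"
  )
}

#' @export
print.excursion_fit <- function(x, ...) {
  cat(sprintf("<excursion_fit> RMSE = %.4g V, %s (%d iterations)\n",
              x$rmse, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  print(x$estimates)
  invisible(x)
}

#' Compare model and Shannon current limits over a design grid
#'
#' Evaluates the diameter-scaled model limit and Shannon's limit on the
#' full factorial grid of diameters and pulse widths.
#'
#' @param model An [excursion_model].
#' @param limits A [safety_limits] carrying the diameter scaling and
#'   Shannon k.
#' @param diameters Diameters, m.
#' @param t_pws Pulse widths, s.
#' @return Data frame with `diameter_m`, `t_pw_s`, `i_limit_model_a`,
#'   `i_limit_shannon_a`, `ratio` (model / Shannon), one row per grid
#'   point.
#' @export
compare_to_shannon <- function(model, limits, diameters, t_pws) {
  stopifnot(inherits(model, "excursion_model"),
            inherits(limits, "safety_limits"))
  grid <- expand.grid(diameter_m = diameters, t_pw_s = t_pws,
                      KEEP.OUT.ATTRS = FALSE)
  t_model_units <- convert_unit(grid$t_pw_s, "s", model$units_decl[["t"]])
  i_model <- current_limit_vs_diameter(limits, model, grid$diameter_m,
                                       t_model_units)
  i_model_a <- convert_unit(i_model, model$units_decl[["i"]], "A")
  i_shannon <- shannon_limit(grid$diameter_m, grid$t_pw_s, limits$shannon_k)
  data.frame(
    diameter_m = grid$diameter_m,
    t_pw_s = grid$t_pw_s,
    i_limit_model_a = i_model_a,
    i_limit_shannon_a = i_shannon,
    ratio = i_model_a / i_shannon
  )
}

#' Electrode geometry
#'
#' @param diameter Disc contact diameter, m; > 0.
#' @param separation Bipolar center-to-center separation, m; must be >=
#'   `diameter` when given.
#' @param contact_class `"micro"` or `"macro"`; selects which empirical
#'   charge threshold applies in [check_pulse()].
#' @return An object of class `electrode_geometry`.
#' @export
electrode_geometry <- function(diameter, separation = NULL,
                               contact_class = c("micro", "macro")) {
  contact_class <- match.arg(contact_class)
  if (!is.numeric(diameter) || length(diameter) != 1L ||
      !is.finite(diameter) || diameter <= 0) {
    stop("`diameter` must be a single positive length (m)", call. = FALSE)
  }
  if (!is.null(separation)) {
    if (!is.numeric(separation) || length(separation) != 1L ||
        !is.finite(separation) || separation < diameter) {
      stop("`separation` must be >= `diameter` for a bipolar pair (m)",
           call. = FALSE)
    }
  }
  structure(
    list(diameter = diameter, separation = separation,
         contact_class = contact_class, shape = "disc"),
    class = "electrode_geometry"
  )
}

#' Safety check of a stimulation pulse
#'
#' Computes the charge per phase and the geometric charge density (disc
#' area \eqn{\pi D^2 / 4}) of a pulse and compares against the empirical
#' thresholds: charge per phase vs 4 nC for micro-contacts, charge density
#' vs 30 uC/cm^2 for macro-contacts.  When an excursion model and an
#' imaginary-impedance value are supplied, the predicted excursion is also
#' compared with the electrolysis limit `e_mc`; otherwise the report
#' carries a notice that only charge checks were performed.
#'
#' A quantity within relative `tol` of its threshold is flagged
#' `"at_limit"`.
#'
#' @param geom An [electrode_geometry].
#' @param wave A [pulse_waveform].
#' @param limits A [safety_limits].
#' @param model Optional [excursion_model] for the excursion check.
#' @param z_imag_mag Imaginary impedance magnitude for the excursion check,
#'   in the model's declared impedance unit.
#' @param tol Relative tolerance for the `"at_limit"` flag.
#' @return A list of class `safety_report`: charge per phase (C), charge
#'   density (C/cm^2), thresholds, statuses (`"pass"`, `"at_limit"`,
#'   `"fail"`), optional excursion block, overall `status`, `notices`.
#' @export
check_pulse <- function(geom, wave, limits, model = NULL,
                        z_imag_mag = NULL, tol = 1e-6) {
  stopifnot(inherits(geom, "electrode_geometry"),
            inherits(wave, "pulse_waveform"),
            inherits(limits, "safety_limits"))
  q_c <- charge_per_phase(wave)
  area_cm2 <- pi * (geom$diameter * 100)^2 / 4
  density <- q_c / area_cm2

  flag <- function(value, threshold) {
    if (value == 0) return("pass")
    r <- value / threshold
    if (abs(r - 1) <= tol) "at_limit" else if (r < 1) "pass" else "fail"
  }
  notices <- character(0)
  checks <- list()
  if (geom$contact_class == "micro") {
    thr <- limits$q_per_phase_micro * 1e-9
    checks$charge_per_phase <- list(
      value_c = q_c, threshold_c = thr, status = flag(q_c, thr))
  } else {
    thr <- limits$q_density_macro * 1e-6
    checks$charge_density <- list(
      value_c_cm2 = density, threshold_c_cm2 = thr,
      status = flag(density, thr))
  }
  if (!is.null(model)) {
    if (is.null(z_imag_mag)) {
      stop("supply `z_imag_mag` with `model` for the excursion check",
           call. = FALSE)
    }
    i_model <- convert_unit(abs(wave$amplitude), "A",
                            model$units_decl[["i"]])
    t_model <- convert_unit(wave$t_pw, "s", model$units_decl[["t"]])
    v_pred <- predict_excursion(model, i_model, t_model, z_imag_mag)
    checks$excursion <- list(
      predicted_v = v_pred, e_mc_v = abs(limits$e_mc),
      status = flag(v_pred, abs(limits$e_mc)))
  } else {
    notices <- c(notices,
                 "no excursion model supplied: charge-only checks")
  }
  statuses <- vapply(checks, function(x) x$status, character(1))
  overall <- if (any(statuses == "fail")) "fail"
             else if (any(statuses == "at_limit")) "at_limit"
             else "pass"
  structure(
    list(charge_per_phase_c = q_c,
         charge_density_c_cm2 = density,
         area_cm2 = area_cm2,
         contact_class = geom$contact_class,
         checks = checks, status = overall, notices = notices),
    class = "safety_report"
  )
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf("<safety_report> %s contact: overall %s\n",
              x$contact_class, toupper(x$status)))
  cat(sprintf("  charge/phase: %.4g nC; density: %.4g uC/cm^2\n",
              x$charge_per_phase_c * 1e9, x$charge_density_c_cm2 * 1e6))
  for (nm in names(x$checks)) {
    cat(sprintf("  %s: %s\n", nm, x$checks[[nm]]$status))
  }
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}
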