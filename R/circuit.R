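#' Electrode-tissue interface equivalent circuit
#'
#' The interface is modeled as a series combination of the bulk conduction
#' resistance, the spreading (access) resistance at the contact perimeter,
#' and a capacitive charge-injection network: the double-layer CPE in
#' parallel with a faradaic branch (charge-transfer resistance in series
#' with a faradaic CPE),
#' \deqn{Z(f) = R_{bulk} + R_{spread} + \left[ Z_{C_{DL}} \parallel
#'   (R_{CT} + Z_{C_F}) \right].}
#'
#' `r_ct = Inf` flags a purely capacitive interface (the faradaic branch is
#' open and `c_f` is ignored).  `c_dl = NULL` removes the double-layer
#' branch; with both branches absent the circuit is the bare series
#' resistance.
#'
#' @param c_dl Double-layer [cpe_params], or `NULL` for no double-layer
#'   branch.
#' @param r_ct Charge-transfer resistance, ohm.  May be `Inf` (purely
#'   capacitive interface); must otherwise be >= 0.
#' @param c_f Faradaic-branch [cpe_params], or `NULL` for a purely resistive
#'   faradaic branch.
#' @param r_spread Spreading resistance, ohm, >= 0.
#' @param r_bulk Bulk conduction resistance, ohm, >= 0.
#' @param label Free-text provenance (material, diameter, medium).
#'
#' @return An object of class `interface_circuit`.
#' @examples
#' circ <- interface_circuit(
#'   c_dl = cpe_params(2e-7, 0.85), r_ct = 2e5,
#'   c_f = cpe_params(1e-6, 0.7), r_spread = 5e3, r_bulk = 1e3
#' )
#' interface_impedance(circ, c(10, 100, 1000))
#' @export
interface_circuit <- function(c_dl, r_ct = Inf, c_f = NULL,
                              r_spread = 0, r_bulk = 0, label = "") {
  if (!is.null(c_dl) && !inherits(c_dl, "cpe_params")) {
    stop("`c_dl` must be a cpe_params object or NULL", call. = FALSE)
  }
  if (!is.numeric(r_ct) || length(r_ct) != 1L || is.na(r_ct) || r_ct < 0) {
    stop("`r_ct` must be a single number >= 0 (Inf allowed)", call. = FALSE)
  }
  if (!is.null(c_f) && !inherits(c_f, "cpe_params")) {
    stop("`c_f` must be a cpe_params object or NULL", call. = FALSE)
  }
  for (nm in c("r_spread", "r_bulk")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single finite number >= 0 (ohm)", nm),
           call. = FALSE)
    }
  }
  structure(
    list(c_dl = c_dl, r_ct = r_ct, c_f = c_f,
         r_spread = r_spread, r_bulk = r_bulk, label = as.character(label)),
    class = "interface_circuit"
  )
}

#' @export
print.interface_circuit <- function(x, ...) {
  cat("<interface_circuit>", if (nzchar(x$label)) x$label else "(unlabeled)",
      "\n")
  if (is.null(x$c_dl)) {
    cat("  C_DL    : (absent)\n")
  } else {
    cat(sprintf("  C_DL    : Q = %.4g S*s^n, n = %.3g\n",
                x$c_dl$q_coeff, x$c_dl$n_exp))
  }
  cat(sprintf("  R_CT    : %s\n",
              if (is.infinite(x$r_ct)) "Inf (purely capacitive)"
              else sprintf("%.4g ohm", x$r_ct)))
  if (!is.infinite(x$r_ct)) {
    if (is.null(x$c_f)) {
      cat("  C_F     : (absent)\n")
    } else {
      cat(sprintf("  C_F     : Q = %.4g S*s^n, n = %.3g\n",
                  x$c_f$q_coeff, x$c_f$n_exp))
    }
  }
  cat(sprintf("  R_spread: %.4g ohm\n  R_bulk  : %.4g ohm\n",
              x$r_spread, x$r_bulk))
  invisible(x)
}

#' Frequency-indexed complex impedance spectrum
#'
#' @param freqs Frequencies, Hz; strictly positive and sorted ascending.
#' @param z_complex Complex impedance per frequency, ohm.
#' @param meta Named list of provenance metadata (label, units, conditions).
#'
#' @return An object of class `impedance_spectrum`: a data frame with
#'   columns `freq_hz` and `z_ohm` (complex) and a `meta` attribute.
#'   Magnitude and phase views are available via [spectrum_bode()].
#' @export
impedance_spectrum <- function(freqs, z_complex, meta = list()) {
  if (!is.numeric(freqs) || length(freqs) < 1L || any(!is.finite(freqs)) ||
      any(freqs <= 0)) {
    stop("`freqs` must be positive finite frequencies (Hz)", call. = FALSE)
  }
  if (is.unsorted(freqs, strictly = TRUE)) {
    stop("`freqs` must be strictly ascending", call. = FALSE)
  }
  if (length(z_complex) != length(freqs)) {
    stop("`freqs` and `z_complex` must have the same length", call. = FALSE)
  }
  z_complex <- as.complex(z_complex)
  if (any(!is.finite(Re(z_complex))) || any(!is.finite(Im(z_complex)))) {
    stop("`z_complex` contains NaN or infinite entries", call. = FALSE)
  }
  out <- data.frame(freq_hz = as.numeric(freqs))
  out$z_ohm <- z_complex
  attr(out, "meta") <- meta
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}

#' Bode view of an impedance spectrum
#'
#' @param spec An [impedance_spectrum].
#' @return Data frame with `freq_hz`, `z_mag_ohm`, `z_phase_deg` (capacitive
#'   phase negative).
#' @export
spectrum_bode <- function(spec) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  data.frame(
    freq_hz = spec$freq_hz,
    z_mag_ohm = Mod(spec$z_ohm),
    z_phase_deg = Arg(spec$z_ohm) * 180 / pi
  )
}

#' @export
print.impedance_spectrum <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<impedance_spectrum> %d points, %.4g Hz - %.4g Hz\n",
              nrow(x), min(x$freq_hz), max(x$freq_hz)))
  if (!is.null(meta$label)) cat("  label:", meta$label, "\n")
  invisible(x)
}

# Impedance of the parallel charge-injection network alone (0 if absent).
parallel_network_impedance <- function(circ, freqs) {
  y <- rep(0 + 0i, length(freqs))
  any_branch <- FALSE
  if (!is.null(circ$c_dl)) {
    y <- y + 1 / cpe_impedance(circ$c_dl, freqs)
    any_branch <- TRUE
  }
  if (!is.infinite(circ$r_ct)) {
    zf <- if (is.null(circ$c_f)) 0 + 0i else cpe_impedance(circ$c_f, freqs)
    y <- y + 1 / (circ$r_ct + zf)
    any_branch <- TRUE
  }
  if (!any_branch) rep(0 + 0i, length(freqs)) else 1 / y
}

#' Impedance spectrum of an interface circuit
#'
#' Evaluates the full circuit
#' \eqn{Z(f) = R_{bulk} + R_{spread} + [Z_{C_{DL}} \parallel (R_{CT} + Z_{C_F})]}
#' on a frequency grid.  At high frequency the CPE branches short and
#' \eqn{Z \to R_{bulk} + R_{spread}}; with `r_ct = Inf` the parallel network
#' reduces to the double-layer CPE alone.
#'
#' @param circ An [interface_circuit].
#' @param freqs Frequencies, Hz; positive, strictly ascending.
#' @return An [impedance_spectrum].
#' @export
interface_impedance <- function(circ, freqs) {
  if (!inherits(circ, "interface_circuit")) {
    stop("`circ` must be an interface_circuit", call. = FALSE)
  }
  if (length(freqs) == 0L) {
    stop("frequency grid is empty", call. = FALSE)
  }
  z <- circ$r_bulk + circ$r_spread + parallel_network_impedance(circ, freqs)
  impedance_spectrum(freqs, z, meta = list(label = circ$label))
}

#' Spreading (access) resistance of a disc contact
#'
#' Current crowding at the perimeter of a disc contact of diameter \eqn{D}
#' in a medium of resistivity \eqn{\rho} gives the access resistance
#' \eqn{R = \rho / (2 D)}, which scales as \eqn{1/D}.
#'
#' @param resistivity Medium resistivity, ohm*m; > 0.
#' @param diameter Contact diameter, m; > 0.
#' @return Spreading resistance, ohm.
#' @examples
#' spreading_resistance(0.7, 30e-6)  # ~11.7 kohm
#' @export
spreading_resistance <- function(resistivity, diameter) {
  if (!is.numeric(resistivity) || any(!is.finite(resistivity)) ||
      any(resistivity <= 0)) {
    stop("`resistivity` must be positive and finite (ohm*m)", call. = FALSE)
  }
  if (!is.numeric(diameter) || any(!is.finite(diameter)) ||
      any(diameter <= 0)) {
    stop("`diameter` must be positive and finite (m)", call. = FALSE)
  }
  resistivity / (2 * diameter)
}
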