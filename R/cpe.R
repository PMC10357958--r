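#' Constant-phase element parameters
#'
#' A constant-phase element (CPE) is the nonideal capacitor used to describe
#' the double layer and faradaic branches of an electrode-tissue interface.
#' Its impedance is \eqn{Z(\omega) = 1 / (Q (j\omega)^n)}, giving a
#' frequency-independent phase of \eqn{-n \cdot 90^\circ}.  With `n_exp = 1`
#' the element is an ideal capacitor of capacitance `q_coeff`.
#'
#' @param q_coeff CPE magnitude coefficient, in S·s^n (the admittance
#'   magnitude at \eqn{\omega = 1} rad/s).  Must be positive.
#' @param n_exp Dimensionless fractional exponent in (0, 1].
#'
#' @return An object of class `cpe_params`.
#' @examples
#' cpe <- cpe_params(q_coeff = 1e-7, n_exp = 0.8)
#' cpe_impedance(cpe, 1000)
#' @export
cpe_params <- function(q_coeff, n_exp) {
  if (!is.numeric(q_coeff) || length(q_coeff) != 1L || !is.finite(q_coeff) ||
      q_coeff <= 0) {
    stop("`q_coeff` must be a single positive finite number (S*s^n)",
         call. = FALSE)
  }
  if (!is.numeric(n_exp) || length(n_exp) != 1L || !is.finite(n_exp) ||
      n_exp <= 0 || n_exp > 1) {
    stop("`n_exp` must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(q_coeff = q_coeff, n_exp = n_exp), class = "cpe_params")
}

#' @export
print.cpe_params <- function(x, ...) {
  cat(sprintf("<cpe_params> Q = %.6g S*s^n, n = %.4g\n", x$q_coeff, x$n_exp))
  invisible(x)
}

#' Impedance of a constant-phase element
#'
#' Evaluates \eqn{Z(f) = 1 / (Q (j 2\pi f)^n)}.  The phase is
#' \eqn{-n \cdot 90^\circ} at every frequency and the magnitude is
#' \eqn{1 / (Q (2\pi f)^n)}.
#'
#' @param cpe A [cpe_params] object.
#' @param freq Frequency or vector of frequencies, Hz.  Must be positive.
#'
#' @return Complex impedance in ohms, one value per frequency.
#' @export
cpe_impedance <- function(cpe, freq) {
  if (!inherits(cpe, "cpe_params")) {
    stop("`cpe` must be a cpe_params object", call. = FALSE)
  }
  if (!is.numeric(freq) || length(freq) < 1L || any(!is.finite(freq)) ||
      any(freq <= 0)) {
    stop("`freq` must be positive and finite (Hz)", call. = FALSE)
  }
  w <- 2 * pi * freq
  1 / (cpe$q_coeff * (1i * w)^cpe$n_exp)
}
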