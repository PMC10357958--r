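#' Complex nonlinear least-squares fit of an interface circuit to a spectrum
#'
#' Fits the interface-circuit parameters to a measured (or synthetic)
#' impedance spectrum by minimizing stacked, weighted real and imaginary
#' residuals with the Levenberg-Marquardt algorithm.  Positive parameters
#' (CPE coefficients, resistances) are fitted in log space; CPE exponents
#' are bounded to `n_bounds` (default \[0.3, 1\]) to avoid Warburg-like
#' degeneracy.  A seeded 5-way multistart (the initial guess plus four
#' log-uniform perturbations in ×1/3 ... ×3) guards against local minima;
#' the lowest weighted residual wins, ties broken by fewer iterations then
#' lexicographic parameter order.
#'
#' The branch structure follows `init`: an infinite `r_ct` in `init` fits a
#' purely capacitive interface.  Because `r_spread` and `r_bulk` enter the
#' impedance only through their sum, a single series resistance is
#' estimated and split back in the proportion given by `init`.
#'
#' @param spec An [impedance_spectrum] with at least 8 points spanning at
#'   least 2 frequency decades.
#' @param init An [interface_circuit] initial guess (within bounds).
#' @param weighting Residual weighting: `"modulus"` (divide by `|Z|` per
#'   point; default, appropriate for spectra spanning decades), `"unit"`,
#'   or `"proportional"` (real part by `|Re Z|`, imaginary by `|Im Z|`).
#' @param seed Integer seed for the multistart jitter (fit is deterministic
#'   given `seed`).
#' @param n_bounds Bounds on CPE exponents during fitting.
#' @param n_starts Number of multistart points (the init plus
#'   `n_starts - 1` perturbations).
#'
#' @return An object of class `eis_fit` with elements `circuit` (fitted
#'   [interface_circuit]), `residual_norm` (weighted residual 2-norm),
#'   `estimates` (data frame of parameter values with approximate standard
#'   errors), `converged`, `n_iter`, `weighting`, `seed`.
#' @export
fit_interface <- function(spec, init,
                          weighting = c("modulus", "unit", "proportional"),
                          seed = 1L, n_bounds = c(0.3, 1), n_starts = 5L) {
  stopifnot(inherits(spec, "impedance_spectrum"),
            inherits(init, "interface_circuit"))
  weighting <- match.arg(weighting)
  if (nrow(spec) < 8L) {
    stop("need at least 8 frequency points", call. = FALSE)
  }
  span <- log10(max(spec$freq_hz) / min(spec$freq_hz))
  if (span < 2) {
    stop("degenerate spectrum: frequencies must span at least 2 decades",
         call. = FALSE)
  }
  has_dl <- !is.null(init$c_dl)
  has_far <- !is.infinite(init$r_ct)
  has_cf <- has_far && !is.null(init$c_f)
  if (!has_dl && !has_far) {
    stop("`init` has no fittable branch elements", call. = FALSE)
  }

  r_series0 <- init$r_spread + init$r_bulk
  spread_frac <- if (r_series0 > 0) init$r_spread / r_series0 else 1

  # parameter packing: logs for positive magnitudes, raw for exponents
  nm <- character(0); th0 <- numeric(0)
  lo <- numeric(0); hi <- numeric(0)
  add <- function(name, value, lo_v, hi_v) {
    nm <<- c(nm, name); th0 <<- c(th0, value)
    lo <<- c(lo, lo_v); hi <<- c(hi, hi_v)
  }
  if (has_dl) {
    add("log_q_dl", log(init$c_dl$q_coeff), -60, 60)
    add("n_dl", init$c_dl$n_exp, n_bounds[1], n_bounds[2])
  }
  if (has_far) add("log_r_ct", log(max(init$r_ct, 1e-6)), -60, 60)
  if (has_cf) {
    add("log_q_f", log(init$c_f$q_coeff), -60, 60)
    add("n_f", init$c_f$n_exp, n_bounds[1], n_bounds[2])
  }
  add("log_r_series", log(max(r_series0, 1e-9)), -60, 60)

  unpack <- function(th) {
    th <- as.list(stats::setNames(th, nm))
    interface_circuit(
      c_dl = if (has_dl) cpe_params(exp(th$log_q_dl), th$n_dl) else NULL,
      r_ct = if (has_far) exp(th$log_r_ct) else Inf,
      c_f = if (has_cf) cpe_params(exp(th$log_q_f), th$n_f) else NULL,
      r_spread = exp(th$log_r_series) * spread_frac,
      r_bulk = exp(th$log_r_series) * (1 - spread_frac),
      label = init$label
    )
  }

  zm <- spec$z_ohm
  wts <- switch(weighting,
    modulus = {
      w <- 1 / pmax(Mod(zm), .Machine$double.eps)
      c(w, w)
    },
    unit = rep(1, 2L * length(zm)),
    proportional = c(1 / pmax(abs(Re(zm)), .Machine$double.eps),
                     1 / pmax(abs(Im(zm)), .Machine$double.eps))
  )
  resid_fn <- function(th) {
    zh <- interface_impedance(unpack(th), spec$freq_hz)$z_ohm
    c(Re(zh - zm), Im(zh - zm)) * wts
  }

  is_log <- grepl("^log_", nm)
  set.seed(as.integer(seed))
  starts <- vector("list", n_starts)
  starts[[1L]] <- th0
  for (s in seq_len(n_starts - 1L)) {
    jit <- th0
    jit[is_log] <- jit[is_log] + stats::runif(sum(is_log), -log(3), log(3))
    jit[!is_log] <- pmin(pmax(
      jit[!is_log] * exp(stats::runif(sum(!is_log), -log(3), log(3))),
      lo[!is_log]), hi[!is_log])
    starts[[s + 1L]] <- jit
  }

  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st, lower = lo, upper = hi, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rn <- sqrt(sum(fit$fvec^2))
    cand <- list(fit = fit, rn = rn, n_iter = fit$niter)
    if (is.null(best) || rn < best$rn ||
        (rn == best$rn && (cand$n_iter < best$n_iter ||
          (cand$n_iter == best$n_iter &&
           paste(fit$par, collapse = ",") <
             paste(best$fit$par, collapse = ","))))) {
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("all multistart fits failed", call. = FALSE)
  }
  fit <- best$fit
  th <- stats::setNames(as.numeric(fit$par), nm)

  # approximate SEs via the Jacobian at the solution (delta method for logs)
  se <- rep(NA_real_, length(th))
  jtj <- try(fit$hessian, silent = TRUE)
  if (!inherits(jtj, "try-error") && !is.null(jtj)) {
    dof <- max(length(fit$fvec) - length(th), 1L)
    s2 <- sum(fit$fvec^2) / dof
    cv <- try(solve(jtj) * s2, silent = TRUE)
    if (!inherits(cv, "try-error")) {
      se <- sqrt(pmax(diag(cv), 0))
    }
  }
  value <- ifelse(is_log, exp(th), th)
  se_nat <- ifelse(is_log, se * value, se)
  estimates <- data.frame(
    param = sub("^log_", "", nm),
    value = as.numeric(value),
    se = as.numeric(se_nat),
    row.names = NULL
  )
  structure(
    list(circuit = unpack(th),
         residual_norm = best$rn,
         estimates = estimates,
         converged = fit$info %in% 1:4,
         n_iter = best$n_iter,
         weighting = weighting,
         seed = as.integer(seed)),
    class = "eis_fit"
  )
}

#' @export
print.eis_fit <- function(x, ...) {
  cat(sprintf("<eis_fit> weighted residual norm %.4g (%s weighting), %s\n",
              x$residual_norm, x$weighting,
              if (x$converged) "converged" else "NOT converged"))
  print(x$estimates)
  invisible(x)
}

#' Power-law scaling of impedance with contact diameter
#'
#' Fits \eqn{|Z_{imag}| = \alpha D^{-d_1}} by least squares on
#' \eqn{(\log D, \log |Z_{imag}|)}.  The exponent \eqn{d_1} captures how
#' the electrochemical impedance varies with the electrode diameter and
#' feeds the diameter-scaled current-limit equation.
#'
#' @param diameters Contact diameters, m; at least 3 distinct positive
#'   values.
#' @param z_imag_mag Magnitude of the imaginary impedance at the reference
#'   frequency, ohm; positive, same length as `diameters`.
#' @param ref_freq_hz Reference frequency the impedances were taken at
#'   (metadata; default 1 kHz, the usual reporting frequency).
#'
#' @return An object of class `diameter_scaling` with `alpha_coeff`
#'   (prefactor: ohm at D = 1 m on this convention), `d1_exp`, `r_squared`,
#'   `n`, `ref_freq_hz`.
#' @export
fit_diameter_scaling <- function(diameters, z_imag_mag, ref_freq_hz = 1000) {
  if (!is.numeric(diameters) || !is.numeric(z_imag_mag) ||
      length(diameters) != length(z_imag_mag)) {
    stop("`diameters` and `z_imag_mag` must be numeric vectors of equal length",
         call. = FALSE)
  }
  if (any(!is.finite(diameters)) || any(diameters <= 0) ||
      any(!is.finite(z_imag_mag)) || any(z_imag_mag <= 0)) {
    stop("diameters and impedances must be positive and finite",
         call. = FALSE)
  }
  if (length(unique(diameters)) < 3L) {
    stop("need at least 3 distinct diameters", call. = FALSE)
  }
  fit <- stats::lm(log(z_imag_mag) ~ log(diameters))
  cf <- stats::coef(fit)
  ly <- log(z_imag_mag)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  structure(
    list(alpha_coeff = exp(unname(cf[1L])),
         d1_exp = -unname(cf[2L]),
         r_squared = r2,
         n = length(diameters),
         ref_freq_hz = ref_freq_hz),
    class = "diameter_scaling"
  )
}

#' @export
print.diameter_scaling <- function(x, ...) {
  cat(sprintf(
    "<diameter_scaling> |Z_imag| = %.4g * D^-%.4g (R^2 = %.4f, n = %d, ref %g Hz)\n",
    x$alpha_coeff, x$d1_exp, x$r_squared, x$n, x$ref_freq_hz))
  invisible(x)
}

#' Bode overlay plot of a spectrum and an optional fitted circuit
#'
#' @param spec An [impedance_spectrum].
#' @param circuit Optional [interface_circuit] to overlay.
#' @param file Optional path; when given, a PNG is written atomically.
#' @return Invisibly, `NULL`.
#' @export
plot_bode <- function(spec, circuit = NULL, file = NULL) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  draw <- function() {
    bode <- spectrum_bode(spec)
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(bode$freq_hz, bode$z_mag_ohm, log = "xy", type = "p",
                   pch = 1, xlab = "frequency (Hz)", ylab = "|Z| (ohm)")
    if (!is.null(circuit)) {
      fg <- 10^seq(log10(min(bode$freq_hz)), log10(max(bode$freq_hz)),
                   length.out = 200)
      zf <- interface_impedance(circuit, fg)
      graphics::lines(fg, Mod(zf$z_ohm), col = "red")
    }
    graphics::plot(bode$freq_hz, bode$z_phase_deg, log = "x", type = "p",
                   pch = 1, xlab = "frequency (Hz)", ylab = "phase (deg)")
    if (!is.null(circuit)) {
      graphics::lines(fg, Arg(zf$z_ohm) * 180 / pi, col = "red")
    }
  }
  if (is.null(file)) {
    draw()
  } else {
    tmp <- tempfile(tmpdir = dirname(file), fileext = ".png")
    grDevices::png(tmp, width = 800, height = 600)
    ok <- try(draw(), silent = TRUE)
    grDevices::dev.off()
    if (inherits(ok, "try-error")) {
      unlink(tmp)
      stop(ok, call. = FALSE)
    }
    file.rename(tmp, file)
  }
  invisible(NULL)
}
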