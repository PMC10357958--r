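#' Current-clamped stimulation pulse waveform
#'
#' Rectangular, cathodic-first pulse train.  `amplitude` is the cathodic
#' phase amplitude and is negative by convention (a positive value is
#' accepted and negated with a warning).  Charge per phase is exactly
#' `|amplitude| * t_pw` for rectangular phases.
#'
#' @param amplitude Cathodic phase current, A (negative by convention).
#' @param t_pw Phase width, s; > 0.
#' @param interphase_gap Gap between cathodic and anodic phases, s; >= 0.
#' @param biphasic If `TRUE` (default) a charge-balanced anodic phase
#'   follows each cathodic phase.
#' @param n_pulses Number of pulses; >= 1.
#' @param dt Simulation timestep, s; must satisfy `dt <= t_pw / 50` so each
#'   phase is resolved by at least 50 samples.
#'
#' @return An object of class `pulse_waveform`.
#' @export
pulse_waveform <- function(amplitude, t_pw, interphase_gap = 0,
                           biphasic = TRUE, n_pulses = 1L,
                           dt = t_pw / 1000) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L ||
      !is.finite(amplitude)) {
    stop("`amplitude` must be a single finite current (A)", call. = FALSE)
  }
  if (amplitude > 0) {
    warning("cathodic-first convention: `amplitude` made negative")
    amplitude <- -amplitude
  }
  if (!is.numeric(t_pw) || length(t_pw) != 1L || !is.finite(t_pw) ||
      t_pw <= 0) {
    stop("`t_pw` must be a single positive phase width (s)", call. = FALSE)
  }
  if (!is.numeric(interphase_gap) || length(interphase_gap) != 1L ||
      !is.finite(interphase_gap) || interphase_gap < 0) {
    stop("`interphase_gap` must be >= 0 (s)", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive timestep (s)", call. = FALSE)
  }
  if (dt > t_pw / 50) {
    stop("`dt` must be <= t_pw / 50 to resolve each phase", call. = FALSE)
  }
  n_pulses <- as.integer(n_pulses)
  if (is.na(n_pulses) || n_pulses < 1L) {
    stop("`n_pulses` must be >= 1", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, t_pw = t_pw,
         interphase_gap = interphase_gap, biphasic = isTRUE(biphasic),
         n_pulses = n_pulses, dt = dt),
    class = "pulse_waveform"
  )
}

#' Charge per phase of a rectangular pulse
#'
#' @param wave A [pulse_waveform].
#' @return `|amplitude| * t_pw`, coulomb.
#' @export
charge_per_phase <- function(wave) {
  stopifnot(inherits(wave, "pulse_waveform"))
  abs(wave$amplitude) * wave$t_pw
}

#' Sampled current vector of a pulse waveform
#'
#' Samples the pulse train at its timestep.  Each pulse is a cathodic phase,
#' an optional interphase gap at zero current, an anodic phase when
#' `biphasic`, and a trailing settling interval of one phase width at zero
#' current.
#'
#' @param wave A [pulse_waveform].
#' @return Numeric vector of currents (A), one per timestep; sample k is the
#'   current over `((k-1) dt, k dt]`.
#' @export
waveform_current <- function(wave) {
  stopifnot(inherits(wave, "pulse_waveform"))
  n_ph <- round(wave$t_pw / wave$dt)
  n_gap <- round(wave$interphase_gap / wave$dt)
  one <- c(rep(wave$amplitude, n_ph),
           rep(0, n_gap),
           if (wave$biphasic) rep(-wave$amplitude, n_ph),
           rep(0, n_ph))
  rep(one, wave$n_pulses)
}

# Grunwald-Letnikov binomial weights w_j = (-1)^j choose(n, j), j = 0..m.
gl_weights <- function(n_exp, m) {
  w <- numeric(m + 1L)
  w[1L] <- 1
  if (m >= 1L) {
    for (j in seq_len(m)) {
      w[j + 1L] <- w[j] * (1 - (n_exp + 1) / j)
    }
  }
  w
}

#' Time-domain response of an interface circuit to an arbitrary current
#'
#' Integrates the circuit's fractional-order dynamics under a prescribed
#' current using a Grunwald-Letnikov discretization of the CPE constitutive
#' law \eqn{i(t) = Q \, d^n v / dt^n}.  The circuit starts from rest
#' (zero interface polarization).  At each step the discrete fractional
#' derivatives turn into convolutions over the voltage history, leaving a
#' small linear system for the new branch voltages.
#'
#' @param circ An [interface_circuit].
#' @param i_t Numeric vector of injected currents (A), one per timestep.
#' @param dt Timestep, s.
#' @param max_samples Sample-count ceiling; exceeding it is an error
#'   advising a larger `dt` or shorter waveform.
#'
#' @return Data frame with `time_s`, `i_inj_a`, `v_elec_v` (total electrode
#'   voltage including the series IR drop) and `v_interface_v` (polarization
#'   across the parallel charge-injection network).
#' @export
simulate_current_response <- function(circ, i_t, dt, max_samples = 2e6) {
  if (!inherits(circ, "interface_circuit")) {
    stop("`circ` must be an interface_circuit", call. = FALSE)
  }
  n <- length(i_t)
  if (n < 1L) stop("`i_t` is empty", call. = FALSE)
  if (n > max_samples) {
    stop(sprintf(paste0(
      "simulation needs %d samples, above the ceiling of %g; ",
      "increase `dt` or shorten the waveform"), n, max_samples),
      call. = FALSE)
  }
  has_dl <- !is.null(circ$c_dl)
  has_far <- !is.infinite(circ$r_ct)
  has_cf <- has_far && !is.null(circ$c_f)
  r_ct <- circ$r_ct
  rs <- circ$r_spread + circ$r_bulk

  a1 <- if (has_dl) circ$c_dl$q_coeff * dt^(-circ$c_dl$n_exp) else 0
  a2 <- if (has_cf) circ$c_f$q_coeff * dt^(-circ$c_f$n_exp) else 0
  w1 <- if (has_dl) gl_weights(circ$c_dl$n_exp, n) else NULL
  w2 <- if (has_cf) gl_weights(circ$c_f$n_exp, n) else NULL

  vp <- numeric(n)   # across parallel network
  vcf <- numeric(n)  # across faradaic CPE
  for (k in seq_len(n)) {
    h1 <- if (has_dl && k > 1L) {
      a1 * sum(w1[2:k] * vp[(k - 1L):1L])
    } else 0
    h2 <- if (has_cf && k > 1L) {
      a2 * sum(w2[2:k] * vcf[(k - 1L):1L])
    } else 0
    i_k <- i_t[k]
    if (has_dl && !has_far) {
      vp[k] <- (i_k - h1) / a1
    } else if (has_dl && has_cf) {
      # i = a1 vp + h1 + if ; if = (a2 vp + h2) / (1 + a2 r_ct)
      denom <- a1 + a2 / (1 + a2 * r_ct)
      vp[k] <- (i_k - h1 - h2 / (1 + a2 * r_ct)) / denom
      i_f <- (a2 * vp[k] + h2) / (1 + a2 * r_ct)
      vcf[k] <- vp[k] - i_f * r_ct
    } else if (has_dl && has_far && !has_cf) {
      vp[k] <- (i_k - h1) / (a1 + 1 / r_ct)
    } else if (!has_dl && has_cf) {
      vcf[k] <- (i_k - h2) / a2
      vp[k] <- i_k * r_ct + vcf[k]
    } else if (!has_dl && has_far) {
      vp[k] <- i_k * r_ct
    } else {
      vp[k] <- 0
    }
  }
  data.frame(
    time_s = dt * seq_len(n),
    i_inj_a = i_t,
    v_elec_v = i_t * rs + vp,
    v_interface_v = vp
  )
}

#' Voltage transient of a current-clamped stimulation pulse
#'
#' Simulates the electrode voltage excursion produced by a rectangular
#' (biphasic) current pulse train through an interface circuit.  For a pure
#' CPE under constant current \eqn{I} from rest, the response follows the
#' fractional step-response closed form
#' \eqn{V(t) = I t^n / (Q \, \Gamma(1 + n))}, which the discretization
#' reproduces within its convergence tolerance.
#'
#' @inheritParams simulate_current_response
#' @param wave A [pulse_waveform].
#' @return Data frame as in [simulate_current_response].
#' @export
pulse_transient <- function(circ, wave, max_samples = 2e6) {
  if (!inherits(wave, "pulse_waveform")) {
    stop("`wave` must be a pulse_waveform", call. = FALSE)
  }
  simulate_current_response(circ, waveform_current(wave), wave$dt,
                            max_samples = max_samples)
}

#' Extreme voltage excursions of a transient
#'
#' @param trace Data frame from [pulse_transient()] (column `v_elec_v` used
#'   unless `column` says otherwise), or a plain numeric voltage vector.
#' @param baseline Baseline voltage subtracted before taking extrema, V.
#' @param column Voltage column to scan when `trace` is a data frame.
#' @return List with `cathodal` (most negative excursion, V), `anodal`
#'   (most positive, V), and the sample indices `i_cathodal`, `i_anodal`
#'   (and times `t_cathodal`, `t_anodal` when available) at which they
#'   occur.
#' @export
excursion_extrema <- function(trace, baseline = 0, column = "v_elec_v") {
  if (is.data.frame(trace)) {
    if (!column %in% names(trace)) {
      stop(sprintf("column `%s` not found in trace", column), call. = FALSE)
    }
    v <- trace[[column]]
    tt <- trace[["time_s"]]
  } else {
    v <- as.numeric(trace)
    tt <- NULL
  }
  if (length(v) == 0L) stop("empty trace", call. = FALSE)
  dv <- v - baseline
  ic <- which.min(dv)
  ia <- which.max(dv)
  out <- list(cathodal = dv[ic], anodal = dv[ia],
              i_cathodal = ic, i_anodal = ia)
  if (!is.null(tt)) {
    out$t_cathodal <- tt[ic]
    out$t_anodal <- tt[ia]
  }
  out
}
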