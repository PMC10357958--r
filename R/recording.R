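#' Recording front-end description
#'
#' Lumped description of the acquisition front end: amplifier input
#' resistance and capacitance, parasitic lead shunt capacitance, recording
#' bandwidth, and the digitization budget (sample rate, bit depth, channel
#' count).
#'
#' @param r_in Amplifier input resistance, ohm; > 0 (clinical amplifiers
#'   are around 16 Mohm at 1 kHz).
#' @param c_in Amplifier input capacitance, F; > 0.
#' @param c_parasitic Lead shunt / inter-lead capacitance, F; > 0.
#' @param bandwidth Recording bandwidth, Hz; > 0.
#' @param sample_rate Samples per second per channel; a rate below twice
#'   the bandwidth warns (sub-Nyquist).
#' @param bit_depth Bits per sample.
#' @param n_channels Channel count.
#' @return An object of class `recording_front_end`.
#' @export
recording_front_end <- function(r_in = 16e6, c_in = 1e-13,
                                c_parasitic = 1e-13, bandwidth = 10e3,
                                sample_rate = 30e3, bit_depth = 16L,
                                n_channels = 1L) {
  vals <- c(r_in = r_in, c_in = c_in, c_parasitic = c_parasitic,
            bandwidth = bandwidth, sample_rate = sample_rate,
            bit_depth = bit_depth, n_channels = n_channels)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  if (sample_rate < 2 * bandwidth) {
    warning("sample_rate below 2 * bandwidth (sub-Nyquist)")
  }
  structure(
    list(r_in = r_in, c_in = c_in, c_parasitic = c_parasitic,
         bandwidth = bandwidth, sample_rate = sample_rate,
         bit_depth = as.integer(bit_depth),
         n_channels = as.integer(n_channels)),
    class = "recording_front_end"
  )
}

#' Coupling coefficient of an electrode into a front end
#'
#' The recorded amplitude relative to the signal at the electrode surface,
#' from the voltage divider formed by the electrode impedance against the
#' amplifier input shunt
#' \eqn{Z_{shunt} = R_{in} \parallel 1/(j\omega (C_{in} + C_{par}))}:
#' \deqn{CC = \frac{|Z_{shunt}|}{|Z_{shunt} + Z_{elec}|}.}
#' CC is 1 at zero electrode impedance and decreases monotonically with
#' `|z_elec|` at fixed phase.
#'
#' @param z_elec Electrode impedance at `freq` (complex or real), ohm.
#' @param fe A [recording_front_end].
#' @param freq Frequency, Hz; > 0.
#' @return Coupling coefficient in (0, 1].
#' @export
coupling_coefficient <- function(z_elec, fe = recording_front_end(),
                                 freq = 1000) {
  stopifnot(inherits(fe, "recording_front_end"))
  if (!is.numeric(freq) || any(freq <= 0) || any(!is.finite(freq))) {
    stop("`freq` must be positive and finite (Hz)", call. = FALSE)
  }
  w <- 2 * pi * freq
  z_c <- 1 / (1i * w * (fe$c_in + fe$c_parasitic))
  z_shunt <- 1 / (1 / fe$r_in + 1 / z_c)
  Mod(z_shunt) / Mod(z_shunt + z_elec)
}

#' Electrode-to-amplifier impedance ratio
#'
#' The magnitude of the electrode impedance relative to the amplifier
#' input resistance, in percent.  A contact whose impedance approaches
#' 10 percent of the input impedance already attenuates and delays the
#' recorded signal appreciably.
#'
#' @param z_elec Electrode impedance, ohm (complex or magnitude).
#' @param r_in Amplifier input resistance, ohm.
#' @return Ratio in percent.
#' @examples
#' impedance_ratio(1.5e6, 16e6)  # 9.375
#' @export
impedance_ratio <- function(z_elec, r_in = 16e6) {
  if (any(!is.finite(Mod(z_elec))) || any(r_in <= 0)) {
    stop("inputs must be finite with r_in > 0", call. = FALSE)
  }
  100 * Mod(z_elec) / r_in
}

#' Johnson-Nyquist thermal noise of an interface
#'
#' Integrates the one-sided thermal noise density over the band:
#' \eqn{v_{rms} = \sqrt{4 k_B T \int \mathrm{Re}\,Z(f) \, df}} (trapezoidal
#' rule on the supplied profile).  For a flat resistance this reduces to
#' \eqn{\sqrt{4 k_B T R B}}.
#'
#' @param freqs Frequencies over the band, Hz; at least 2 points,
#'   ascending, or a length-2 band `c(f_lo, f_hi)` when `re_z` is a single
#'   flat resistance.
#' @param re_z Real part of the impedance at each frequency, ohm; >= 0.
#'   A single value is treated as flat across the band.
#' @param temperature Temperature, K (default 300).
#' @return RMS noise voltage, V.
#' @examples
#' thermal_noise_rms(c(0, 10e3), 400e3)  # ~8.14 uV
#' @export
thermal_noise_rms <- function(freqs, re_z, temperature = 300) {
  kb <- 1.380649e-23
  if (length(freqs) < 2L || any(!is.finite(freqs)) || any(freqs < 0) ||
      is.unsorted(freqs)) {
    stop("`freqs` must be >= 2 ascending finite frequencies (Hz)",
         call. = FALSE)
  }
  if (any(!is.finite(re_z)) || any(re_z < 0)) {
    stop("Re{Z} must be finite and >= 0 everywhere (non-physical input)",
         call. = FALSE)
  }
  if (temperature <= 0) stop("`temperature` must be > 0 (K)", call. = FALSE)
  if (length(re_z) == 1L) re_z <- rep(re_z, length(freqs))
  if (length(re_z) != length(freqs)) {
    stop("`re_z` must be length 1 or match `freqs`", call. = FALSE)
  }
  integral <- sum(diff(freqs) * (utils::head(re_z, -1) + utils::tail(re_z, -1)) / 2)
  sqrt(4 * kb * temperature * integral)
}

#' Conduction delay between two contacts
#'
#' @param separation Contact separation, m; > 0.
#' @param speed Signal propagation speed, m/s; > 0 (typical neural
#'   propagation is 0.2-1 m/s).
#' @return Delay, s.
#' @examples
#' conduction_delay(50e-6, 1)  # 50 us
#' @export
conduction_delay <- function(separation, speed) {
  if (any(!is.finite(separation)) || any(separation <= 0)) {
    stop("`separation` must be positive and finite (m)", call. = FALSE)
  }
  if (any(!is.finite(speed)) || any(speed <= 0)) {
    stop("`speed` must be positive and finite (m/s)", call. = FALSE)
  }
  separation / speed
}

#' Acquisition data rate
#'
#' `n_channels * sample_rate * bit_depth`, computed in exact integer-valued
#' arithmetic.
#'
#' @param fe A [recording_front_end] (or the individual fields below).
#' @param n_channels,sample_rate,bit_depth Overrides taken from `fe` when
#'   missing.
#' @return List with `bits_per_s` (exact) and `gbps` (decimal 10^9
#'   gigabits per second).
#' @examples
#' data_rate(n_channels = 4096, sample_rate = 30e3, bit_depth = 16)
#' @export
data_rate <- function(fe = NULL, n_channels = NULL, sample_rate = NULL,
                      bit_depth = NULL) {
  if (!is.null(fe)) {
    stopifnot(inherits(fe, "recording_front_end"))
    if (is.null(n_channels)) n_channels <- fe$n_channels
    if (is.null(sample_rate)) sample_rate <- fe$sample_rate
    if (is.null(bit_depth)) bit_depth <- fe$bit_depth
  }
  vals <- c(n_channels = n_channels, sample_rate = sample_rate,
            bit_depth = bit_depth)
  if (any(!is.finite(vals)) || any(vals <= 0) ||
      any(vals != round(vals))) {
    stop("channels, sample rate and bit depth must be positive integers",
         call. = FALSE)
  }
  bits <- as.numeric(n_channels) * as.numeric(sample_rate) *
    as.numeric(bit_depth)
  list(bits_per_s = bits, gbps = bits / 1e9)
}

#' Capacitive crosstalk bound between adjacent leads
#'
#' Worst-case divider bound for the fraction of a neighboring channel's
#' signal coupled through the inter-lead capacitance:
#' \deqn{\frac{|Z_{elec}|}{|Z_{elec}| + |1/(j\omega C_{interlead})|}.}
#' High-impedance contacts and larger parasitic capacitance both raise the
#' bound.
#'
#' @param z_elec Electrode impedance magnitude (or complex), ohm.
#' @param c_interlead Inter-lead capacitance, F; >= 0.
#' @param freq Frequency, Hz; > 0.
#' @return Crosstalk bound in \[0, 1).
#' @export
crosstalk_bound <- function(z_elec, c_interlead, freq = 1000) {
  if (any(!is.finite(Mod(z_elec))) || any(Mod(z_elec) < 0)) {
    stop("`z_elec` must be finite", call. = FALSE)
  }
  if (any(!is.finite(c_interlead)) || any(c_interlead < 0)) {
    stop("`c_interlead` must be >= 0 (F)", call. = FALSE)
  }
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("`freq` must be positive (Hz)", call. = FALSE)
  }
  if (all(c_interlead == 0)) {
    return(rep(0, max(length(z_elec), length(c_interlead))))
  }
  zc <- 1 / (2 * pi * freq * c_interlead)
  Mod(z_elec) / (Mod(z_elec) + zc)
}
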