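# Unit tables shared by the excursion model, safety checks and the CLI.
# Suffixes are case-sensitive ("Mohm" vs "mohm" would differ; only the
# documented spellings are accepted).

.unit_si <- c(
  # time -> s
  s = 1, ms = 1e-3, us = 1e-6,
  # length -> m
  m = 1, cm = 1e-2, mm = 1e-3, um = 1e-6, nm = 1e-9,
  # resistance -> ohm
  ohm = 1, kohm = 1e3, Mohm = 1e6,
  # current -> A
  A = 1, mA = 1e-3, uA = 1e-6, nA = 1e-9,
  # voltage -> V
  V = 1, mV = 1e-3, uV = 1e-6,
  # charge -> C
  C = 1, mC = 1e-3, uC = 1e-6, nC = 1e-9,
  # frequency -> Hz
  Hz = 1, kHz = 1e3, MHz = 1e6
)

#' Convert a value between documented units
#'
#' Converts between the unit spellings used throughout the package
#' (`us`, `ms`, `s`, `um`, `mm`, `cm`, `m`, `ohm`, `kohm`, `Mohm`, `uA`,
#' `mA`, `A`, `V`, `mV`, `nC`, `uC`, `C`, `Hz`, `kHz`, ...).  Spellings are
#' case-sensitive.
#'
#' @param value Numeric value(s).
#' @param from,to Unit names.
#' @return `value` expressed in `to` units.
#' @examples
#' convert_unit(200, "us", "s")
#' @export
convert_unit <- function(value, from, to) {
  for (u in c(from, to)) {
    if (!u %in% names(.unit_si)) {
      stop(sprintf("unknown unit `%s`", u), call. = FALSE)
    }
  }
  value * .unit_si[[from]] / .unit_si[[to]]
}

#' Parse a unit-suffixed quantity string
#'
#' Parses strings such as `"200us"`, `"30kohm"`, `"1.5Mohm"` or `"20uA"`
#' into an SI value.  A bare number (no suffix) is rejected: physical CLI
#' inputs must carry units.
#'
#' @param text Quantity string.
#' @param expect Optional vector of admissible unit names; parsing a
#'   quantity in other units is an error.
#' @return Named numeric: the value in SI units, named by the SI unit
#'   parsed (`s`, `m`, `ohm`, `A`, `V`, `C`, or `Hz`).
#' @export
parse_quantity <- function(text, expect = NULL) {
  m <- regmatches(text,
                  regexec("^([0-9.eE+-]+)([A-Za-z]+)$", trimws(text)))[[1L]]
  if (length(m) != 3L) {
    stop(sprintf("cannot parse quantity `%s` (unit suffix required)", text),
         call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(m[2L]))
  unit <- m[3L]
  if (is.na(value)) {
    stop(sprintf("cannot parse number in `%s`", text), call. = FALSE)
  }
  if (!unit %in% names(.unit_si)) {
    stop(sprintf("unknown unit `%s` in `%s`", unit, text), call. = FALSE)
  }
  if (!is.null(expect) && !unit %in% expect) {
    stop(sprintf("quantity `%s` must use one of: %s", text,
                 paste(expect, collapse = ", ")), call. = FALSE)
  }
  base <- c(s = "s", ms = "s", us = "s",
            m = "m", cm = "m", mm = "m", um = "m", nm = "m",
            ohm = "ohm", kohm = "ohm", Mohm = "ohm",
            A = "A", mA = "A", uA = "A", nA = "A",
            V = "V", mV = "V", uV = "V",
            C = "C", mC = "C", uC = "C", nC = "C",
            Hz = "Hz", kHz = "Hz", MHz = "Hz")[[unit]]
  stats::setNames(value * .unit_si[[unit]], base)
}
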