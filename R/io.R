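# Columnar text and JSON readers/writers.  All writes are atomic: content
# goes to a temp file in the destination directory which is then renamed,
# so an interrupted run never leaves a half-written output.

write_atomic <- function(lines, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    stop(sprintf("could not move temporary file onto `%s`", path),
         call. = FALSE)
  }
  invisible(path)
}

split_csv_line <- function(line) trimws(strsplit(line, ",", fixed = TRUE)[[1L]])

read_columnar <- function(path, expected_header) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: `%s`", path), call. = FALSE)
  }
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 2L) {
    stop(sprintf("`%s` has no data rows", path), call. = FALSE)
  }
  header <- split_csv_line(lines[1L])
  if (!identical(header, expected_header)) {
    stop(sprintf("`%s`: header is `%s` but `%s` expected", path,
                 paste(header, collapse = ","),
                 paste(expected_header, collapse = ",")), call. = FALSE)
  }
  ncol <- length(expected_header)
  rows <- matrix(NA_real_, nrow = length(lines) - 1L, ncol = ncol)
  for (i in seq_len(length(lines) - 1L)) {
    cells <- split_csv_line(lines[i + 1L])
    vals <- suppressWarnings(as.numeric(cells))
    if (length(cells) != ncol || any(is.na(vals)) || any(is.nan(vals))) {
      stop(sprintf("`%s`: malformed row at line %d: `%s`", path,
                   lineno[i + 1L], lines[i + 1L]), call. = FALSE)
    }
    rows[i, ] <- vals
  }
  colnames(rows) <- expected_header
  list(data = as.data.frame(rows), comments = raw[grepl("^\\s*#", raw)])
}

#' Read an impedance spectrum from columnar text
#'
#' Two dialects are supported: `"complex"` with header
#' `freq_hz,z_real_ohm,z_imag_ohm` and `"bode"` with header
#' `freq_hz,z_mag_ohm,z_phase_deg` (phase in degrees, capacitive phase
#' negative).  Comment lines start with `#`.  Malformed or NaN cells raise
#' an error naming the line; unsorted frequencies are sorted with a
#' warning.
#'
#' @param path File path.
#' @param dialect `"complex"` or `"bode"`.
#' @return An [impedance_spectrum].
#' @export
read_spectrum <- function(path, dialect = c("complex", "bode")) {
  dialect <- match.arg(dialect)
  header <- switch(dialect,
    complex = c("freq_hz", "z_real_ohm", "z_imag_ohm"),
    bode = c("freq_hz", "z_mag_ohm", "z_phase_deg"))
  parsed <- read_columnar(path, header)
  df <- parsed$data
  if (is.unsorted(df$freq_hz, strictly = TRUE)) {
    warning(sprintf("`%s`: frequencies not sorted ascending; sorting", path))
    df <- df[order(df$freq_hz), , drop = FALSE]
  }
  z <- if (dialect == "complex") {
    complex(real = df$z_real_ohm, imaginary = df$z_imag_ohm)
  } else {
    ph <- df$z_phase_deg * pi / 180
    complex(modulus = df$z_mag_ohm, argument = ph)
  }
  impedance_spectrum(df$freq_hz, z,
                     meta = list(path = path, dialect = dialect))
}

#' Write an impedance spectrum to columnar text
#'
#' @param spec An [impedance_spectrum].
#' @param path Destination path (written atomically).
#' @param dialect `"complex"` or `"bode"`.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(spec, path, dialect = c("complex", "bode")) {
  stopifnot(inherits(spec, "impedance_spectrum"))
  dialect <- match.arg(dialect)
  meta <- attr(spec, "meta")
  head_lines <- character(0)
  if (!is.null(meta$label) && nzchar(meta$label)) {
    head_lines <- sprintf("# label: %s", meta$label)
  }
  fmt <- function(x) sprintf("%.12g", x)
  body <- if (dialect == "complex") {
    c("freq_hz,z_real_ohm,z_imag_ohm",
      paste(fmt(spec$freq_hz), fmt(Re(spec$z_ohm)), fmt(Im(spec$z_ohm)),
            sep = ","))
  } else {
    c("freq_hz,z_mag_ohm,z_phase_deg",
      paste(fmt(spec$freq_hz), fmt(Mod(spec$z_ohm)),
            fmt(Arg(spec$z_ohm) * 180 / pi), sep = ","))
  }
  write_atomic(c(head_lines, body), path)
}

#' Read an excursion dataset from columnar text
#'
#' Format: optional `#` comments, a mandatory units line
#' `# units: uA,us,kohm,V` (current, pulse width, impedance, voltage), and
#' a CSV body with header `i_inj,t_pw,z_imag_ohm,v_elec`.  The `z_imag_ohm`
#' column name is historical; the units line governs the impedance unit.
#'
#' @param path File path.
#' @return An [excursion_dataset].
#' @export
read_excursion_dataset <- function(path) {
  parsed <- read_columnar(path, c("i_inj", "t_pw", "z_imag_ohm", "v_elec"))
  units_line <- grep("^\\s*#\\s*units\\s*:", parsed$comments, value = TRUE)
  if (length(units_line) != 1L) {
    stop(sprintf("`%s`: exactly one `# units: i,t,z,V` line is required",
                 path), call. = FALSE)
  }
  units <- split_csv_line(sub("^\\s*#\\s*units\\s*:", "", units_line))
  if (length(units) != 4L || units[4L] != "V") {
    stop(sprintf("`%s`: units line must declare 4 units ending in V", path),
         call. = FALSE)
  }
  df <- parsed$data
  excursion_dataset(df$i_inj, df$t_pw, df$z_imag_ohm, df$v_elec,
                    units_decl = c(i = units[1L], t = units[2L],
                                   z = units[3L]),
                    meta = list(path = path))
}

#' Write an excursion dataset to columnar text
#'
#' @param data An [excursion_dataset].
#' @param path Destination path (written atomically).
#' @return Invisibly, `path`.
#' @export
write_excursion_dataset <- function(data, path) {
  stopifnot(inherits(data, "excursion_dataset"))
  u <- attr(data, "units_decl")
  fmt <- function(x) sprintf("%.12g", x)
  lines <- c(
    sprintf("# units: %s,%s,%s,V", u[["i"]], u[["t"]], u[["z"]]),
    "i_inj,t_pw,z_imag_ohm,v_elec",
    paste(fmt(data$i_inj), fmt(data$t_pw), fmt(data$z_imag),
          fmt(data$v_elec), sep = ",")
  )
  write_atomic(lines, path)
}

#' Serialize an interface circuit to JSON
#'
#' Keys carry explicit units (`q_coeff_s_sn`, `r_ct_ohm`, ...).  An
#' infinite charge-transfer resistance is stored as the string `"inf"`.
#'
#' @param circ An [interface_circuit].
#' @param path Optional destination; when given the JSON is written
#'   atomically and the path returned invisibly.
#' @return JSON string, or the path when `path` is given.
#' @export
circuit_to_json <- function(circ, path = NULL) {
  stopifnot(inherits(circ, "interface_circuit"))
  obj <- list(
    label = circ$label,
    c_dl = if (!is.null(circ$c_dl)) {
      list(q_coeff_s_sn = circ$c_dl$q_coeff, n_exp = circ$c_dl$n_exp)
    },
    r_ct_ohm = if (is.infinite(circ$r_ct)) "inf" else circ$r_ct,
    c_f = if (!is.null(circ$c_f)) {
      list(q_coeff_s_sn = circ$c_f$q_coeff, n_exp = circ$c_f$n_exp)
    },
    r_spread_ohm = circ$r_spread,
    r_bulk_ohm = circ$r_bulk
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  write_atomic(as.character(txt), path)
}

#' Deserialize an interface circuit from JSON
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return An [interface_circuit].
#' @export
circuit_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  mk_cpe <- function(x) {
    if (is.null(x)) NULL else cpe_params(x$q_coeff_s_sn, x$n_exp)
  }
  r_ct <- obj$r_ct_ohm
  if (is.character(r_ct)) {
    if (!identical(tolower(r_ct), "inf")) {
      stop(sprintf("unrecognized r_ct_ohm value `%s`", r_ct), call. = FALSE)
    }
    r_ct <- Inf
  }
  interface_circuit(
    c_dl = mk_cpe(obj$c_dl), r_ct = r_ct, c_f = mk_cpe(obj$c_f),
    r_spread = obj$r_spread_ohm %||% 0,
    r_bulk = obj$r_bulk_ohm %||% 0,
    label = obj$label %||% ""
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an excursion model to JSON
#'
#' @param model An [excursion_model].
#' @param path Optional destination (atomic write).
#' @return JSON string, or `path`.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "excursion_model"))
  obj <- list(
    a_v = model$a_scale, b_coeff = model$b_coeff,
    k2_exp = model$k2_exp, k4_exp = model$k4_exp, k6_exp = model$k6_exp,
    units = as.list(model$units_decl)
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  write_atomic(as.character(txt), path)
}

#' Deserialize an excursion model from JSON
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return An [excursion_model].
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  excursion_model(obj$a_v, obj$b_coeff, obj$k2_exp, obj$k4_exp, obj$k6_exp,
                  units_decl = unlist(obj$units))
}

#' Serialize safety limits to JSON
#'
#' @param limits A [safety_limits].
#' @param path Optional destination (atomic write).
#' @return JSON string, or `path`.
#' @export
limits_to_json <- function(limits, path = NULL) {
  stopifnot(inherits(limits, "safety_limits"))
  obj <- list(
    e_mc_v = limits$e_mc,
    alpha_coeff_ohm = limits$alpha_coeff,
    d1_exp = limits$d1_exp,
    shannon_k = limits$shannon_k,
    q_density_macro_uc_cm2 = limits$q_density_macro,
    q_per_phase_micro_nc = limits$q_per_phase_micro,
    diameter_range_m = limits$diameter_range
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  write_atomic(as.character(txt), path)
}

#' Deserialize safety limits from JSON
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A [safety_limits].
#' @export
limits_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  safety_limits(
    e_mc = obj$e_mc_v,
    alpha_coeff = obj$alpha_coeff_ohm,
    d1_exp = obj$d1_exp,
    shannon_k = obj$shannon_k %||% 1.85,
    q_density_macro = obj$q_density_macro_uc_cm2 %||% 30,
    q_per_phase_micro = obj$q_per_phase_micro_nc %||% 4,
    diameter_range = obj$diameter_range_m
  )
}
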