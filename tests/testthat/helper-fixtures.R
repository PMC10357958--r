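# Shared fixtures: a reference circuit and excursion model with all
# branches active, used by the fitting and simulation tests.

ref_circuit <- function() {
  interface_circuit(
    c_dl = cpe_params(2e-7, 0.85), r_ct = 2e5,
    c_f = cpe_params(1e-6, 0.7), r_spread = 5e3, r_bulk = 1e3,
    label = "reference"
  )
}

ref_circuit_init <- function() {
  # truth perturbed roughly x2 per parameter, the usual starting point
  interface_circuit(
    c_dl = cpe_params(4e-7, 0.9), r_ct = 4e5,
    c_f = cpe_params(2e-6, 0.6), r_spread = 1.2e4, r_bulk = 0,
    label = "init"
  )
}

circuit_param_vec <- function(circ) {
  c(q_dl = circ$c_dl$q_coeff, n_dl = circ$c_dl$n_exp, r_ct = circ$r_ct,
    q_f = circ$c_f$q_coeff, n_f = circ$c_f$n_exp,
    r_series = circ$r_spread + circ$r_bulk)
}

ref_excursion_model <- function() {
  excursion_model(0.5, 0.005, 1, 0.5, 0.5,
                  units_decl = c(i = "uA", t = "us", z = "kohm"))
}

ref_excursion_grids <- function() {
  list(i = c(10, 20, 50, 100, 200), t = c(50, 100, 200, 500),
       z = c(10, 30, 100))
}
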