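{
  "label": "PEDOT_PSS preset (|Z| = 30000 ohm at 1 kHz)",
  "c_dl": {
    "q_coeff_s_sn": 8.32175333661898e-09,
    "n_exp": 0.95
  },
  "r_ct_ohm": "inf",
  "c_f": null,
  "r_spread_ohm": 1500,
  "r_bulk_ohm": 1500
}
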