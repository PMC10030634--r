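{
  "name": "table3a",
  "variant": "three_comp_eq15",
  "coefficients": {
    "r_l": 0.33306,
    "r_g": 0.06799,
    "e_lev": -8.61143,
    "a_hthhd": -0.00155,
    "b_hthhd": 2.29e-4,
    "a_hth": 21.34836,
    "b_hth": 0.37104,
    "a_hthab": 0.00182,
    "b_hthab": 5.20e-6
  },
  "units": "a_hth, b_hth per thorax area (W m-2 degC-1, W m-2 degC-2); head and abdomen terms absolute (a_* W degC-1, b_* W degC-2); r_l, r_g, e_lev dimensionless",
  "note": "Three-compartment model (9 coefficients): head and abdomen convection driven by thorax-to-head and thorax-to-abdomen temperature differences; published accuracy SD_res = 5.78 mW, adj. R2 = 0.89085, df = 863."
}
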