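{
  "name": "table3b",
  "variant": "three_comp_eq16",
  "coefficients": {
    "r_l": 0.33816,
    "r_g": 0.06758,
    "e_lev": -8.71008,
    "a_hthhd": -0.00167,
    "b_hthhd": 2.34e-4,
    "a_hth": 20.85664,
    "b_hth": 0.38344,
    "h_thab": 0.00195
  },
  "units": "a_hth, b_hth per thorax area (W m-2 degC-1, W m-2 degC-2); head and abdomen terms absolute (a_hthhd W degC-1, b_hthhd W degC-2, h_thab W degC-1); r_l, r_g, e_lev dimensionless",
  "note": "Simplified three-compartment model (constant thorax-abdomen coefficient, 8 coefficients); published accuracy SD_res = 5.78 mW, adj. R2 = 0.89097, df = 864. The published e_lev here (-8.71008) differs from the simplified per-segment set (-7.80027) while sharing its t-value pattern; values are entered as printed."
}
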