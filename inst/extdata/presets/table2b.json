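{
  "name": "table2b",
  "variant": "advanced_eq14",
  "coefficients": {
    "r_l": 0.33816,
    "r_g": 0.06758,
    "e_lev": -7.80027,
    "a_hhd": 55.80168,
    "b_hhd": -8.71008,
    "a_hth": 26.57184,
    "b_hth": 5.28199,
    "h_ab": -22.66916
  },
  "units": "a_*, h_ab in W m-2 degC-1, b_* in W m-2 degC-2; r_l, r_g, e_lev dimensionless",
  "note": "Simplified per-segment model (constant abdomen coefficient, 8 coefficients); published accuracy SD_res = 5.78 mW, adj. R2 = 0.89097, df = 864. Caution: the published e_lev (-7.80027) and b_hhd (-8.71008) values carry t-values that swap places relative to the matching simplified three-compartment set, suggesting a possible transposition in the source table; values are entered as printed, not corrected."
}
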