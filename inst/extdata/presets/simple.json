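{
  "name": "simple",
  "variant": "simple_eq7",
  "coefficients": {
    "r_l": 0.68114,
    "r_g": 0.30352,
    "e_lev": 1.82501,
    "h_b": 12.14393
  },
  "units": "h_b in W m-2 degC-1; r_l, r_g, e_lev dimensionless",
  "note": "Whole-body convection model fitted to the original 872-visit stationary-forager dataset; published accuracy SD_res = 15.3 mW, adj. R2 = 0.24078."
}
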