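{
  "feature_names": ["P_VSA_MR_6_pmix", "Eig02_EA(dm)_pmix", "CATS2D_02_AN_pmix", "BLTF96_pmix", "MATS5s_nmix", "temperature"],
  "intercept": 89.611,
  "coefficients": {
    "P_VSA_MR_6_pmix": 0.405,
    "Eig02_EA(dm)_pmix": -5.034,
    "CATS2D_02_AN_pmix": -23.145,
    "BLTF96_pmix": 8.835,
    "MATS5s_nmix": -25.191,
    "temperature": -0.104
  },
  "se": {
    "(Intercept)": 3.452,
    "P_VSA_MR_6_pmix": 0.026,
    "Eig02_EA(dm)_pmix": 0.874,
    "CATS2D_02_AN_pmix": 3.32,
    "BLTF96_pmix": 0.174,
    "MATS5s_nmix": 2.352,
    "temperature": 0.011
  },
  "stats": {
    "r2": 0.916,
    "r2_adj": 0.915,
    "f_stat": 642.4,
    "n_tr": 360,
    "rho": 60
  },
  "trace": null,
  "version": "published"
}
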