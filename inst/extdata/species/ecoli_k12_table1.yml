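# Escherichia coli K-12 W3110 -- Monod/yield parameters estimated from
# mono-culture mini-bioreactor batch fermentations. Consumption rates (q_max)
# are printed as negative (substrate drawn down); the loader stores their
# magnitude. Enzyme-dynamics constants follow published cybernetic models:
# constitutive/inducible synthesis ratio 0.01, degradation 0.05 1/h,
# induction constant equal to Ks (omitted K_ind defaults to Ks).
name: ecoli
metabolites: [GLU, ACE, ETH]
enzyme_defaults:
  eps_c: 0.01
  eps_i: 1.0
  delta: 0.05
pathways:
  GLU_ferm:
    substrate: GLU
    mu_max: 0.437
    Ks: 0.112
    q_max: -2.640
    Yx: 0.165
    Yp:
      ACE: 0.835
  ACE:
    substrate: ACE
    mu_max: 0.077
    Ks: 0.108
    q_max: -0.630
    Yx: 0.122
  GLU_ox:
    substrate: GLU
    mu_max: 0.234
    Ks: 1.000
    q_max: -1.745
    Yx: 0.134
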