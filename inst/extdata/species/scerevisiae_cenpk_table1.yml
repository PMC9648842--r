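# Saccharomyces cerevisiae CEN.PK 117D -- Monod/yield parameters estimated
# from mono-culture mini-bioreactor batch fermentations. Consumption rates
# (q_max) are printed as negative; the loader stores their magnitude.
# Fermentative byproduct yields saturate the mass bound Yx + sum(Yp) = 1
# (no published split; ethanol is the dominant overflow product of yeast
# fermentation, so it takes three quarters of the non-biomass carbon).
name: scerevisiae
metabolites: [GLU, ACE, ETH]
enzyme_defaults:
  eps_c: 0.01
  eps_i: 1.0
  delta: 0.05
pathways:
  GLU_ferm:
    substrate: GLU
    mu_max: 0.299
    Ks: 0.082
    q_max: -1.648
    Yx: 0.182
    Yp:
      ETH: 0.613
      ACE: 0.205
  ACE:
    substrate: ACE
    mu_max: 0.017
    Ks: 0.007
    q_max: -0.058
    Yx: 0.285
  ETH:
    substrate: ETH
    mu_max: 0.080
    Ks: 0.055
    q_max: -0.276
    Yx: 0.287
  GLU_ox:
    substrate: GLU
    mu_max: 0.221
    Ks: 1.469
    q_max: -3.175
    Yx: 0.070
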