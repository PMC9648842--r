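# comonod

Cybernetic Monod kinetics for microbial co-culture bioreactors.

## The problem

A fast grower (*Escherichia coli*) and a slow grower (*Saccharomyces
cerevisiae*) competing for glucose in a continuous culture do not coexist:
at any fixed dilution rate the bacterium drives the shared substrate below
the level where the yeast can hold its ground, and the yeast washes out.
Both organisms, however, excrete overflow metabolites while growing fast on
glucose — acetate for the bacterium, ethanol and acetate for the yeast —
and both can re-assimilate those byproducts once glucose is gone (the
diauxic shift). Feeding glucose in square-wave *pulses* turns every
feed-off phase into a starvation-and-diauxie episode that transiently
favours the yeast (it alone eats ethanol, and it has far higher affinity
for trace acetate), which can stabilise the co-culture where constant
feeding cannot.

`comonod` is a simulator and calibration toolkit for exactly this setting,
aimed at bioprocess and microbial-ecology work on co-culture stability
under periodic feeding.

## The model

Each species is a set of substrate-assimilation pathways with Monod
kinetics, gated by virtual key enzymes and regulated by cybernetic
matching-law weights against a growth-rate objective. For pathway *i*:

- uptake rate: `r_i = v_i * q_max_i * psi_rel_i * S_i/(Ks_i + S_i) * X`
- growth return: `mu_i = Yx_i * q_max_i * psi_rel_i * S_i/(Ks_i + S_i)`
- allocation weights `u_i = mu_i / sum(mu)` scale inducible key-enzyme
  synthesis; activity weights `v_i = mu_i / max(mu)` gate uptake
- relative enzyme level: `d psi_i/dt =
  (eps_c + u_i * eps_i * S_i/(K'_i + S_i)) / Psi_max_i
  - (delta + mu_tot) * psi_i`, with
  `Psi_max_i = (eps_c + eps_i)/(delta + mu_max_i)`

A per-pathway stoichiometric matrix (`+Yx` biomass row, `-1` own-substrate
row, `+Yp` byproduct rows) assembles uptake into pool dynamics; a constant
volume CSTR dilution term `D(t)` (constant, zero, or square-wave pulsed
with frequency `w` and duty cycle `s`) completes the reactor. Parameters
for the two packaged organisms (seven pathways, from mono-culture batch
fermentations) ship as plain-text species files.

## Worked example

```r
library(comonod)

ec <- ecoli_k12()
sc <- scerevisiae_cenpk()

# low-frequency glucose pulsing: 2 h feed-on, 5.1 h feed-off at D = 0.1/h,
# after a 10 h batch start-up
fp <- feed_program("pulsed", D = 0.1, w = 0.14, s = 0.28, t_start = 10)
fp
#> <feed_program> mode = pulsed, D_on = 0.1 1/h, w = 0.14 1/h, s = 0.28 (on 2.00 h : off 5.14 h), feed from t = 10 h
#>   feed: GLU=30, ACE=0, ETH=0 g/L

traj <- run_pulsed(list(ec, sc), fp, t_end = 80)
fr <- biomass_fractions(traj)
subset(fr, species == "scerevisiae" & t %in% c(0, 20, 40, 60, 80))
#>       t species     fraction defined
#> 1     0 scerevisiae    0.5   TRUE
#> 2    20 scerevisiae    0.156 TRUE
#> 3    40 scerevisiae    0.156 TRUE
#> 4    60 scerevisiae    0.146 TRUE
#> 5    80 scerevisiae    0.136 TRUE

# the same dilution rate without pulsing excludes the yeast
ch <- run_chemostat(list(ec, sc), D = 0.1, t_end = 80)
tail(biomass_fractions(ch)$fraction[biomass_fractions(ch)$species ==
                                      "scerevisiae"], 1)
#> [1] 0.057
```

Under pulsing the yeast holds ~14% of the biomass through 80 h, oscillating
at the pulse period as its ethanol-assimilation enzyme re-induces in every
feed-off phase (`autoplot(traj, "enzymes")` shows the cycle); under
constant dilution it has fallen to ~6% by 80 h and keeps declining. A batch
diagnostic of substrate limitation:

```r
growth_rate_reduction(ec, S0_hi = 20, S0_lo = 1.25)
#> [1] 18.488
```

the percentage by which the maximum instantaneous specific growth rate
drops when the initial glucose charge shrinks from 20 to 1.25 g/L — driven
by the race between key-enzyme induction and substrate depletion.

Other entry points: `coexistence_scan()` sweeps `(D, w, s)` and reports
which feeding profiles keep both species persistent;
`generate_batch_dataset()` / `fit_kinetics()` / `recovery_report()` form
the calibration workflow (synthetic mini-bioreactor batches, bounded
multi-start least squares, parameter-recovery checks); `run_cli()` (and
the wrapper in `inst/scripts/comonod`) exposes the scenarios as
subcommands over YAML run configurations, with run manifests and
resumable scans.

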