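---
title: "Cybernetic Monod modelling of pulsed microbial co-cultures: methods and design choices"
author: "comonod"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`comonod` simulates competition between microbial species that share a pool
of carbon sources in a well-mixed bioreactor. The packaged organisms are
*Escherichia coli* K-12 and *Saccharomyces cerevisiae* CEN.PK growing on
glucose (GLU) and on the overflow metabolites acetate (ACE) and ethanol
(ETH); the framework itself is agnostic about the organisms and metabolites.

Each species carries a set of substrate-assimilation pathways. Pathway $i$
consumes its substrate $S_i$ at the specific rate

$$ r_i \;=\; \nu_i \, q^{\max}_i \, \Psi^{\mathrm{rel}}_i \, H_i \, X,
\qquad H_i = \frac{S_i}{K_{s,i} + S_i}, $$

where $q^{\max}_i$ is the maximal specific consumption rate (g substrate
/ g biomass / h), $H_i$ the Monod saturation factor, $X$ the biomass
concentration, $\Psi^{\mathrm{rel}}_i \in [0,1]$ the relative level of the
pathway's *virtual key enzyme* — a lumped proxy for the whole assimilation
machinery — and $\nu_i$ a cybernetic activity weight (below). A
stoichiometric matrix with one column per pathway ($+Y_x$ on the biomass
row, $-1$ on the consumed substrate row, $+Y_p$ on byproduct rows) converts
the uptake rates into rates of change of biomass and the metabolite pool,
so mass bookkeeping is a single matrix product.

### Matching-law regulation

Cells allocate biosynthetic resources to the pathway machinery that pays
best in growth. The *potential growth return* of pathway $i$ is
$\mu_i = Y_{x,i}\, q^{\max}_i \, \Psi^{\mathrm{rel}}_i H_i$ — deliberately
un-gated by $\nu$, because the matching law compares what pathways *could*
deliver. The weights are

$$ u_i = \frac{\mu_i}{\sum_j \mu_j}, \qquad
   \nu_i = \frac{\mu_i}{\max_j \mu_j}, $$

with $u$ scaling inducible enzyme synthesis (allocation) and $\nu$ scaling
uptake activity (gating). When every return is zero (all substrates
exhausted) the allocation is degenerate; we define $u$ uniform and $\nu$
all ones. The choice is inconsequential for fluxes — the Monod factors are
already zero — and keeps constitutive synthesis spread over pathways so
re-induction is possible when substrate reappears.

### Key-enzyme dynamics

The relative enzyme level of each pathway follows

$$ \frac{d\Psi^{\mathrm{rel}}_i}{dt} =
   \frac{\varepsilon^c + u_i\,\varepsilon^i\, S_i/(K'_i + S_i)}{\Psi^{\max}_i}
   - (\delta + \mu_{\mathrm{tot}})\,\Psi^{\mathrm{rel}}_i,
\qquad
\Psi^{\max}_i = \frac{\varepsilon^c + \varepsilon^i}{\delta + \mu^{\max}_i}, $$

with constitutive and inducible synthesis rates $\varepsilon^c,
\varepsilon^i$, induction constant $K'$, degradation rate $\delta$, and
dilution by the species' realised total growth rate
$\mu_{\mathrm{tot}} = \sum_i \nu_i \mu_i$. $\Psi^{\max}$ is defined so that
the fully allocated, fully induced, maximally growing state is exactly the
fixed point $\Psi^{\mathrm{rel}} = 1$. Enzyme levels then stay in $[0, 1]$
along trajectories whenever $\varepsilon^c \mu^{\max} \le \varepsilon^i
\delta$ — amply satisfied by the defaults below; the test suite exercises
this bound with randomly drawn admissible parameters.

Two genuinely open choices are worth recording:

* **Intensive enzyme variable.** The synthesis term is treated as intensive
  (per biomass). An extensive reading — inducible synthesis proportional to
  the biomass concentration — is available through
  `enzyme_synthesis_scaled_by_biomass = TRUE`, but a relative enzyme level
  bounded by 1 is only well defined for an intensive quantity, so the
  intensive form is the default.
* **Weight placement.** $u$ multiplies the inducible synthesis term and
  $\nu$ the uptake activity. This is the standard matching-law assignment
  and the only one consistent with the two normalisations ($\sum u = 1$
  spreads a synthesis budget; $\max \nu = 1$ gates activity).

### Parameters

Monod/yield constants for the packaged organisms (seven pathways across the
two species) come from mono-culture batch fermentations and ship in
`inst/extdata/species/*.yml`; consumption rates are printed negative there
and stored as positive magnitudes, with the sign carried by the
stoichiometric matrix. Growth, consumption and yield are mutually
consistent, $\mu^{\max} \approx Y_x q^{\max}$; the loader enforces this to
3% rather than 2% because rates printed with two significant digits (the
yeast acetate pathway: $0.285 \times 0.058 = 0.01653$ against a printed
$\mu^{\max} = 0.017$) can deviate by up to ~3% from rounding alone.

Enzyme-dynamics constants are not identifiable from the packaged data and
follow published cybernetic-model practice: $\varepsilon^c / \varepsilon^i
= 0.01$ (weak constitutive background), $\delta = 0.05\,\mathrm{h^{-1}}$,
$K' = K_s$ per pathway. Only the ratio $\varepsilon^c : \varepsilon^i$
matters for the relative dynamics. Initial enzyme state defaults to the
resting-cell constitutive steady state
$(\varepsilon^c/\delta)/\Psi^{\max}$, i.e. a starved inoculum; scenarios
can override it.

Byproduct yields of the fermentative pathways are not separately measured;
the defaults saturate the mass bound $Y_x + \sum Y_p = 1$ (E. coli
fermentation: all non-biomass mass to acetate; yeast fermentation: the
remainder split 3:1 between ethanol and acetate, ethanol being yeast's
dominant overflow product). These are deliberately extreme — they maximise
cross-feeding — and are overridable in the species files.

## Reactor operation

Batch, chemostat and square-wave pulsed feeding are all expressed as a
dilution programme $D(t)$ at constant working volume (outflow = inflow; the
feed-off phase has neither). A pulse programme has on-phase rate $D$,
frequency $w$ (period $1/w$) and duty cycle $s$: on for the first fraction
$s$ of every period. The period average is $sD$. The experimental regimes
correspond to $(w, s) = (0.14, 0.28)$ — 2 h on : 5.1 h off — and
$(0.33, 0.33)$ — 1 h on : 2 h off — at $D = 0.1\,\mathrm{h^{-1}}$. A
parenthetical quirk: the "dilution rate" of a pulsed experiment is read as
the on-phase rate, not the average; `D_is_average = TRUE` selects the other
convention.

Numerics: the joint ODE system (biomasses, metabolite pool, enzyme levels)
is integrated with `deSolve`'s lsoda (default `rtol = 1e-8`,
`atol = 1e-10`), restarted at every pulse edge so the discontinuity in
$D(t)$ is never stepped over — segment-wise integration between exact edge
times makes results reproducible across solver choices. Output is sampled
on a uniform grid (default 0.05 h); concentrations below $10^{-12}$ g/L
are clamped to zero. The right-hand side is evaluated in C for speed, with
a pure-R twin implementation retained and cross-checked in the tests; a
halving of the tolerances moves an 80 h co-culture end state by less than
$10^{-4}$ relative.

With a single pathway and the enzyme level pinned at 1
(`dynamic_enzymes = FALSE`) the system reduces *exactly* to classical
Monod kinetics, which gives two analytic oracles used in testing: the
batch Monod integrator and the chemostat steady state $S^* =
K_s D/(\mu^{\max} - D)$, $X^* = Y_x (S_{feed} - S^*)$. With dynamic
enzymes the steady-state enzyme level sits below 1 (induction saturates
while dilution persists), so the classical formulas hold only in the
pinned-enzyme limit — which is why that limit exists as an option.

## Scenarios and the coexistence scan

`run_batch()`, `run_chemostat()` and `run_pulsed()` wrap the integrator
with the experimental protocols (0.05 g/L inoculum per species standing in
for ~0.1 OD at an assumed 0.5 gDW/L/OD; 10 h batch start-up before
continuous feeding; 30 g/L glucose feed). Species fractions are
biomass-concentration fractions — the model's state. Flow-cytometry event
fractions, the observable of the original experiments, differ by a
per-cell mass factor of roughly fifty between yeast and bacteria, so
comparisons with event-fraction data are qualitative only and no
conversion is attempted.

`coexistence_scan()` sweeps $(D, w, s)$, runs 200 h per grid point
(at least 20 pulse periods for every default frequency), averages each
species' fraction over the final 20% and calls a species persistent above
a 1% averaged fraction. The default grid is $D \in \{0.025, 0.05, 0.075,
0.1, 0.15, 0.2, 0.3\}$, $w, s \in \{0.1, \dots, 0.5\}$. There is no
randomness anywhere in this module; scans are bit-reproducible and can be
checkpointed and resumed.

Two honest limitations of this machinery, both visible in the acceptance
suite:

* **Finite-horizon persistence.** A species declining at, say, 0.2% per
  pulse period still clears the 1% threshold after 200 h. At high on-phase
  rates with small duty cycles ($D = 0.2$–$0.3$, $s \le 0.2$, average
  dilution $\le 0.06\,\mathrm{h^{-1}}$) the yeast is in exactly this slow
  decline, so the scan's "largest coexistence-supporting $D$" lands at the
  top of the grid rather than at $0.1\,\mathrm{h^{-1}}$. A trend-aware
  persistence criterion (or a much longer horizon) would separate these
  quasi-persistent points from the genuinely periodic coexistence observed
  at $D \le 0.1$ with experiment-like duty cycles.
* **Plain Monod uptake only.** Extended uptake laws (product or
  competitive inhibition) are out of scope here; under plain Monod
  kinetics with the packaged parameters, the fermentative glucose pathway
  of *E. coli* offers the best growth return at *every* glucose
  concentration, so the oxidative pathway is never selected, acetate is
  excreted at all dilution rates, and in a chemostat the glucose level
  settles at $S^*$ where *E. coli* still out-grows the yeast. The
  co-culture therefore shows monotone competitive exclusion of the yeast
  from feed start, without the transient yeast recovery seen
  experimentally after glucose exhaustion. The pulsed regimes, which
  periodically let glucose run out completely, do produce the
  ethanol-pathway re-induction and the sustained fraction oscillations
  that motivate the whole approach.

The batch growth-rate-reduction diagnostic (maximum instantaneous specific
growth rate after a 0.5 h burn-in, compared between 20 and 1.25 g/L
charges) is highly sensitive to the enzyme-dynamics constants: it measures
the race between key-enzyme induction — timescale $1/(\delta +
\mu^{\max}) \approx 2$ h under the defaults — and substrate depletion in
the small charge. With the default constants the model yields a reduction
of about 18%; constants that induce faster (as the original calibration's
unpublished values evidently did) yield smaller reductions.

## The synthetic-data generator and the fitting workflow

`generate_batch_dataset()` emulates the parallel mini-bioreactor design
used for parameter estimation: batch mono-cultures at initial glucose
$\{20, 10, 5, 2.5, 1.25\}$ g/L, sampled every 3 h to 30 h (36 h for the
yeast), channels X/GLU/ACE/ETH. Noise is multiplicative Gaussian,
$\mathrm{obs} = \mathrm{true}\,(1 + cv\,z)$, clamped at zero — matching a
dynamic range of three orders of magnitude better than additive noise
would; an optional additive floor (0.01 g/L) mimics an HPLC detection
limit. Replicate wells share the true trajectory and differ only in noise
draws. What the generator does *not* emulate: sampling-induced volume
loss, well-to-well biological variability, instrument drift, and any
model-structure error — so parameter-recovery results certify the
estimator, not the model's fidelity to real cultures.

`fit_kinetics()` estimates Monod/yield parameters of one pathway by
bounded Levenberg–Marquardt least squares over all channels jointly,
each channel weighted by the reciprocal RMS of its observations. Details
that matter:

* Parameters are optimised on the log scale — they are positive scale
  parameters, and the $\mu^{\max}/K_s$ ridge is much better conditioned in
  logs.
* Three deterministic starts (template $\times 1, \times 2, \times 1/2$)
  guard against the bound-adjacent local minima that Monod fits fall into
  from poor starting guesses; the lowest residual wins.
* The consistency family $\mu^{\max} = Y_x q^{\max}$ is enforced by tying
  $q^{\max}$ when it is not itself free, or by a 2%-scale penalty residual
  when it is.
* If the template uses the default induction-constant coupling
  $K' = K_s$, the coupling is preserved while $K_s$ moves; an explicitly
  different $K'$ is treated as a fixed enzyme constant. Enzyme constants
  are never fitted.
* Confidence intervals come from the local quadratic approximation at the
  optimum with an HC3 sandwich middle term (multiplicative noise makes
  residual variance grow with the signal, and leverage shrinks residuals
  at influential points; the plain $(J^\top J)^{-1}$ covariance
  undercovers badly). Intervals are exp-transformed, hence positive and
  asymmetric. In a 50-replicate simulation at $cv = 0.05$ they cover the
  true growth rate ~95% of the time at nominal 95%.

$K_s$ is weakly identified from 3-hourly samples: the sub-$K_s$ window of
a batch lasts under an hour. The declared recovery tolerances reflect
this (10% for $\mu^{\max}$ and $Y_x$, 50% for $K_s$ at 5% noise).

## Problem sizes in the shipped tests

The test-suite simulations are sized to make properties measurable rather
than to reproduce full study scale: statistical properties of the
estimator run on a two-condition, single-pathway design (20 seeds per
noise level for the consistency sweep; 50 for interval coverage); the
coexistence scan runs the full default 175-point grid at a 0.25 h
reporting step; qualitative co-culture checks run 80 h as in the
experiments, orbit-periodicity checks 300 h.
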