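---
title: "A sequential two-step vesicle priming model of target-cell-dependent short-term plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sequential two-step vesicle priming model of target-cell-dependent short-term plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synprime)
```

## The scientific problem

Boutons of the same pyramidal-cell axon release glutamate with an order of
magnitude difference in vesicular release probability (Pv) depending on the
postsynaptic target: connections onto fast-spiking, parvalbumin-type
interneurons (FSIN) are strong and depressing, while connections onto
oriens-lacunosum-moleculare (O-LM) interneurons are weak and strongly
facilitating. `synprime` implements the kinetic model used to dissect this
diversity: a sequential two-step docking/priming scheme in which Pv
factorizes as

Pv = P_fusion x P_TS,

the probability that a fusion-competent vesicle fuses upon an action
potential (AP) times the probability that a docked vesicle is in the
fusion-competent, tightly docked state at rest.

## The model

Release sites cycle through four states:

* **ES** — empty site;
* **LS** — loosely docked, fusion-incompetent vesicle;
* **TS** — tightly docked, fusion-competent vesicle;
* **TSL** — a *labile* tightly docked state, populated transiently from LS
  after each AP.

Between APs the occupancies obey mass-action kinetics

```
dES/dt  = -k1(Ca) ES + b1 LS
dLS/dt  =  k1(Ca) ES - (b1 + k2(Ca)) LS + b2 TS + TSL/b3
dTS/dt  =  k2(Ca) LS - b2 TS
dTSL/dt = -TSL/b3
```

with two calcium-dependent forward rates driven by a spatially averaged
"effective" [Ca2+]:

* docking, saturating: `k1(Ca) = k1_max * Ca / (Ca + K_M)`;
* priming, linear about rest and floored at zero:
  `k2(Ca) = max(0, k2_0 + s2 (Ca - Ca_rest))`.

The effective calcium itself is a resting level (50 nM) plus a fixed
increment per AP (110 nM; 168 nM when AP broadening by 4-AP is modelled)
decaying exponentially with time constant `tau_ca`.

At each AP two instantaneous maps are applied, in this order:

1. **release** — a fraction `p_fusion` of TS and TSL vesicles fuses; their
   sites return to ES;
2. **transfer** — a fraction `f_tsl` of the remaining LS vesicles moves to
   TSL.

Release precedes transfer so that a vesicle entering the labile state cannot
fuse on the AP that created it; the converse ordering would let a single AP
release vesicles that were loosely docked an instant earlier, double-counting
the labile pathway. TSL has no backward route except relaxation to LS with
time constant `b3` (about 40 ms), much faster than TS un-priming (`1/b2`
about 2 s), which is why the labile state contributes to facilitation only at
inter-stimulus intervals shorter than a few tens of milliseconds. `b3` is a
*time constant*, not a rate, despite sharing the `b` naming convention of
`b1`/`b2`; the constructor warns when `b3 >= 1/b2`, which would invert the
priming hierarchy. There is no TSL-to-TS transition and no direct ES-to-TS
docking: only the arrows of the scheme above. Released vesicles return their
sites to ES and are replenished from an effectively unbounded reserve through
`k1`, the only entry path into the cycle.

The calcium dependence of `p_fusion` itself is deliberately omitted; target
cell differences in fusion are carried entirely by the `p_fusion` value.
Receptor saturation/desensitization and EPSC waveform kinetics are out of
scope: the model predicts per-AP peak amplitudes only, linearly scaled from
fractional release by the site count `n_sites` and quantal size `q`.

## Parameters and defaults

Two reference sets are built in. Both share all docking constants and differ
only in `k2_0`, `s2` (about 10-fold lower at O-LM) and `p_fusion`:

| parameter | FSIN | O-LM | units | meaning |
|---|---|---|---|---|
| `b1` | 0.25 | 0.25 | 1/s | un-docking LS to ES |
| `k1_max` | 6 | 6 | 1/s | saturating docking rate |
| `K_M` | 500 | 500 | nM | half-saturation of docking |
| `k2_0` | 0.393 | 0.0376 | 1/s | resting priming rate |
| `s2` | 0.02 | 0.00192 | 1/(s nM) | calcium steepness of priming |
| `b2` | 0.5 | 0.5 | 1/s | un-priming TS to LS |
| `b3` | 0.04 | 0.04 | s | labile-state decay time constant |
| `f_tsl` | 0.2 | 0.2 | — | LS fraction moved to TSL per AP |
| `p_fusion` | 0.6 | 0.36 | — | fusion probability |
| `n_sites` | 24 | 28 | — | docking sites |
| `q` | 32 | 32 | pA | quantal size |

The constrained quantities take their published values: resting tight-state
fractions 0.44 (FSIN) and 0.07 (O-LM) pin `k2_0 = b2 * f/(1-f)`; `p_fusion`
0.6/0.36; `b3` = 40 ms with `b3` about 50 times smaller than `1/b2`, giving
`b2` = 0.5/s; calcium 50/110 nM; `f_tsl` = 0.2; site counts calibrated so the
first response carries 5 quanta (160 pA at `q` = 32 pA) and 0.5 quanta
respectively. The remaining constants (`k1_max`, `K_M`, `s2`, `b1`,
`tau_ca` = 0.1 s) are not published as main-text values; they were fixed once
by requiring that the constrained sets reproduce the measured phenotypes
(frequency-ordered steady-state depression 100 < 20 < 5 Hz with about 0.56
recovery at 110 ms for FSIN; about 3-fold peak facilitation in the complex
protocol for O-LM) and are exposed as ordinary arguments. The O-LM `s2`
scales down by the same factor as `k2_0`, reflecting the finding that a
single joint scaling of the second priming step (plus `p_fusion`) nearly
suffices to convert phenotypes.

```{r phenotypes}
sapply(c(5, 20, 100), function(f)
  steady_state_ratio(simulate_protocol(build_train(15, f), fsin_params())))
max(normalized_amplitudes(
  simulate_protocol(standard_protocols()$complex_rec110, olm_params())))
```

## Numerics

Integration is fixed-step Euler (default `dt` = 0.1 ms) on a precomputed
calcium grid, in compiled code; AP times of all built-in protocols are exact
grid multiples. A classical RK4 scheme and a pure-R Euler path are the
independent cross-checks: per-AP release agrees within 0.5% across all seven
standard protocols, and halving `dt` moves quanta by under 0.1%. Occupancy
conservation is exact in the per-AP maps and monitored during integration;
drift beyond 1e-9, or any occupancy leaving [0, 1], raises an error advising
a smaller step rather than silently renormalizing. The resting state is
computed in closed form from the detailed-balance ratios and is a fixed
point of the integrator to 1e-6 over 10 s.

Fitting minimizes the root-mean-square deviation between model and observed
*per-site release fractions* (quanta divided by `n_sites`), pooled with
equal weight per AP over all protocols of a problem. Data should be
converted to quantal content first; `gta_quanta()` offers the anchored
conversion used for the recorded connections (grand averages rescaled to a
known initial quantal content — 5 quanta FSIN, 0.5 O-LM), which removes the
cohort-strength sampling error that otherwise leaks into the fitted
`p_fusion`/tight-state split. Optimization is bounded quasi-Newton
(`nlminb`) on log-transformed rates with seeded multi-starts (log-uniform
within the bounds: rates 1e-3 to 1e3 /s, `K_M` 1 to 1e4 nM, `b3` 1e-3 to
1 s, fractions 0 to 1). The reported rmsd is always the objective
re-evaluated at the returned estimate. Subset-ladder and nested fits warm
start from the best smaller-subset solution, so best rmsd is non-increasing
in subset size, as the mathematics requires of exact minimizers.

## The synthetic-data generator

`generator_config()`/`generate_dataset()` emulate the *structure* of paired
whole-cell recordings: a lognormal pair-strength factor (mean 1, CV 0.76 to
0.87, matching the recorded first-EPSC variability) multiplying the whole
train of a pair, additive Gaussian trial noise, and optional binomial
sampling of quantal release with `n_sites` trials per AP, from which
transmission failures emerge naturally at weak connections (over half of
first responses fail at O-LM-like parameters). Seeding is hierarchical
(master seed to per-pair substreams), so datasets are bit-reproducible.

The generator does *not* emulate run-down, access-resistance drift,
dendritic filtering, receptor saturation, or trial-to-trial correlations —
all excluded or suppressed experimentally in the recordings it mimics.
Passing recovery tests on synthetic data therefore demonstrates that the
fitting machinery attributes mechanisms correctly when the model class is
correct, not that the model is correct for any particular synapse.

Two validation suites use it. Parameter recovery refits grand averages of
25-pair cohorts (the recorded cohort scale) and requires the resting
tight-state fraction within ±0.07. Mechanism dissociation plants a
fusion-only change (`p_fusion` 0.36 to 0.85 under the raised 168 nM
increment, the modelled consequence of 4-AP) or a priming-only change
(`k2_0`, `s2` jointly scaled so the tight-state fraction moves 0.07 to
0.34, the PDBU effect) and refits under the corresponding scenario
constraints. Because the `p_fusion`/tight-state split is nearly degenerate
at low occupancy, single noisy realizations occasionally prefer a
compensated solution; the dissociation suite therefore simulates larger
cohorts than are feasible in vitro (50 pairs at 50 to 200 trials) and
asserts the median over five fixed-seed replicates. The tight-state ratio
itself is robust in every probed realization; it is the `p_fusion`
attribution that carries realization-to-realization wobble of order 10%,
comparable to the variation the original fits reported between conditions.

## Design choices that were genuinely open

* **Saturation form of docking.** Only "Michaelis-Menten-like" saturation of
  the resting docking rate is specified; the package applies the hyperbola to
  the rate itself, `k1 = k1_max Ca/(Ca + K_M)`, and reports
  `k1_0 = k1(Ca_rest)` as a derived quantity.
* **Priming steepness.** `s2` is read as a linear slope about rest with a
  floor at zero; no saturation is imposed on `k2`, since saturation is named
  only for the docking step.
* **Calcium decay.** The effective-increment decay constant is not a
  main-text value; `tau_ca` = 0.1 s gives residual facilitation at 5 to
  20 Hz but near-complete decay at 1.5 s, and is an ordinary argument.
* **Complex-protocol transition.** The 20 Hz preconditioning train is
  "immediately followed" by the 100 Hz train; the package keeps the 20 Hz
  interval (50 ms) as the transition and exposes it (`complex_gap`).
* **Recovery gaps** are measured from the last conditioning AP to the first
  recovery AP.
* **`f_tsl` is constant** (neither calcium- nor frequency-dependent), the
  simplest reading consistent with the roughly 20% transfer per AP.

## Limitations

Point estimates only: no posterior uncertainty or confidence intervals are
produced, matching the original analysis. The optimizer is local with
multi-starts; pathological objectives can in principle defeat it, which is
why every fit records per-start diagnostics. Absolute rmsd values depend on
the (unpublished) normalization of the original software and are meaningful
within this package only as orderings. The model omits calcium-dependent
fusion, spatial calcium gradients and postsynaptic nonlinearity; where those
matter, `p_fusion` and the effective-calcium parameters absorb them.
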