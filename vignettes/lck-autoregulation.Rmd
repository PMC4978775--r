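---
title: "Modeling LCK autoregulation on reconstituted membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling LCK autoregulation on reconstituted membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lckautoreg)
```

## The model

LCK, the Src-family kinase that initiates T-cell receptor signaling, carries
two regulatory tyrosines: Y394 (activating) and Y505 (inhibitory). On a
supported lipid bilayer LCK phosphorylates both sites in *trans*: the
catalytic domain of one molecule binds an unphosphorylated tyrosine of a
*different* molecule, then either dissociates or transfers a phosphate. CSK
phosphorylates LCK exclusively at Y505. `lckautoreg` implements this as an
explicit Michaelis–Menten reaction network over the four phospho-forms
U394U505, P394U505, U394P505 and P394P505 (abbreviated UU, PU, UP, PP).

Each of the 4 enzyme forms can occupy each of the 4 available substrate
sites (Y394 on UU and UP; Y505 on UU and PU), giving 16 LCK–LCK
enzyme–substrate dimers; CSK adds two more (Y505 on UU and PU). Association
uses a single shared rate `k_on` for all LCK pairs and a single `k_on_csk`
for both CSK pairs — association is diffusion-limited and not expected to be
rate limiting, so per-pair binding strength lives entirely in the
dissociation rates. Every dimer has its own `k_off` and `k_cat`, for
38 kinetic parameters in total (2 + 16 + 2 dissociation + 16 + 2 catalytic).
The active-only network has 23 species (4 free LCK, free CSK, 18 dimers) and
54 unidirectional mass-action reactions; `lck_network()` enumerates it, and
`export_bngl()`/`parse_bngl()` round-trip it as rule-based model text.

Key structural assumptions: no *cis* phosphorylation, no phosphatases, no
spatial effects beyond the 2-D density units (molecules/μm²), and symmetric
dimers (e.g. UU bound to UU) are single species with no statistical factor
of 2 on their rates.

### The catalytically dead variant

The validation experiment replaces half of a high-density LCK pool with an
ATP-binding-site mutant that can be phosphorylated and can bind, but never
catalyzes. We model dead LCK with the same kinetic parameters as active LCK
in both roles — substrate on all four of its sites, and *binder* in the
enzyme role with the catalytic rate forced to zero (so it sequesters
partners). With CSK present this policy yields 77 species; a
substrate-only policy yields 45. The published variant has 73 equations,
which is exactly the binder policy with CSK declared but without CSK binding
rules (8 free LCK + free CSK + 64 dimers) — consistent with a validation
experiment that contains no CSK. `lck_network(include_dead = TRUE,
csk = "species_only")` builds that variant; both policies remain available
and the choice only matters when dead LCK is present.

## Parameters and conditions

`median_params()` is the published ensemble median of the 20 best-fit sets
(also shipped as `inst/extdata/table1_median.json`); `param_table()` adds
the 90% CIs. Six rows of the printed table have CIs that do not bracket
their median (`params_ci_flags()` lists them); they are transcribed
verbatim, not corrected.

The five experimental conditions (`lck_conditions()`) are fixed by the
membrane-reconstitution experiments: 500 LCK/μm² (≈ physiological), 500 LCK
+ 500 CSK, 50 LCK, 50 LCK + 500 CSK for training, and 250 active + 250 dead
LCK for validation. All simulations run 90 min (5400 s) from free,
unphosphorylated molecules; an optional initial phospho-Y505 fraction
(measured ≈1.5%, observed up to ~20%) seeds free U394P505 instead. Units:
densities in molecules/μm², time in seconds internally and minutes at the
I/O boundary, `k_on` in μm²/(molecule·s), all other rates 1/s.

## Simulation and observables

The fitted rates span more than 15 orders of magnitude, so the ODE system
is stiff; `simulate_lck()` integrates with `deSolve::lsoda` at
rtol 1e-8 / atol 1e-12 (tightening 10× moves observables by < 1e-4) using a
compiled mass-action evaluator, with a pure-R `build_rhs()` as the reference
contract. The fitting and sensitivity paths reuse a cached network encoding
through a BDF solver (~2 ms per solve). Integrator undershoot below zero is
clipped in observables only. Total LCK and CSK are conserved exactly by the
stoichiometry and to < 1e-6 relative along every trajectory (checked at run
time).

`observables()` sums phospho-Y394 and phospho-Y505 over *all* species
containing LCK — free and bound, active and dead — and normalizes either by
total LCK (the conserved quantity; default) or by each site's own 90-min
value (`"site90"`), which is how western-blot data normalized to the 90-min
band are expressed. The two agree when a site saturates by 90 min.
`fraction_pp()` reports the doubly phosphorylated fraction; with the median
parameters and 500 LCK/μm², 98.5% of LCK is doubly phosphorylated at 90 min,
and the phospho-Y394 curve leads Y505 everywhere except in the low-LCK +
CSK condition, where the order inverts — the qualitative signature of the
data.

## Synthetic data

`generate_dataset()` emulates quantitative western blots: simulate, sample
on a grid (default 0, 0.25, 0.5, 1, 2, 5, 10, 15, 30, 45, 60, 90 min — the
experiments' sampling times were never tabulated, so the grid spans the
sub-minute burst and the 90-min anchor), multiply each point by independent
lognormal noise with mean 1 and a chosen CV (default 0.1 — band intensities
are positive and their errors scale with signal), then renormalize each
site by its *noisy* 90-min value. Consequently the 90-min point is exactly
1, points with true value 0 stay 0, and a mid-curve point is the ratio of
two independent lognormal factors with CV ≈ √2·cv. What the generator does
not emulate: background subtraction, detector saturation, and correlated
errors between the two sites of one blot.

## Objectives and the two-stage fit

The quantitative objective is the weighted sum of squared residuals with
weights 1/C_exp per point and site; the hybrid objective adds a third sum
over the Y394–Y505 curve difference with weight 1/(C_exp^394 − C_exp^505),
penalizing parameter sets that get the order of the two curves wrong.
Points with C_exp = 0 carry an undefined weight and are excluded (t = 0
carries no blot information); so are difference-term points below a
separation floor. The floor deserves care: the definitional default
(`wssr_hybr(diff_eps = 1e-6)`) only removes exact ties, but on data where
both normalized curves approach 1 the remaining small separations are
noise-dominated and their 1/ΔC weights can dominate the objective —
empirically this displaces the global optimum far from the truth that
generated the data. The fitting campaign therefore uses
`fit_config(diff_eps = 0.05)`: curve-order information below the blot noise
scale is not measurable, so those points are dropped from the difference
term only. The difference-term weight is implemented exactly as written
(signed; squaring removes the sign).

Stage 1 is particle swarm optimization in log10 parameter space —
31 particles, constriction coefficients (inertia 0.729, cognitive = social
= 1.49445; the published description fixes only the particle count and the
50-iteration stall rule, so the remaining hyperparameters are standard
constriction defaults, configurable), velocities clamped to 20% of the box,
termination when the global best stalls for 50 iterations. Failures of the
integrator during search score a penalty of 1e12 and the swarm continues.
Stage 2 refines each swarm result on the quantitative residual vector with
bounded Levenberg–Marquardt (`minpack.lm::nls.lm`; the same bounded
least-squares problem class as trust-region-reflective). Each result is
refined twice — the second run starts from a copy jittered ±0.05 dex, since
the published procedure repeats the refinement without specifying what
differs — and both refinements are kept, so G swarm runs yield 2G ensemble
members. Refinement never returns a point worse than its start.

The published campaign ran 1000 swarm searches over a 1e-20…1e10 box. That
is cluster-scale; the package defaults to a handful of runs, and the
recovery demonstration in the test-suite scales both dimensions
deliberately: 6 free parameters (all others frozen at truth), bounds
1e-8…1e8, 3 swarm runs × 2 refinements on 5%-noise synthetic data. The six
freed parameters — `k_on`, `k_cat_csk_uu`, `k_off_csk_uu`, `k_cat_2`,
`k_cat_15`, `k_cat_9` — are chosen to be both influential (top of the eFAST
ranking) and *individually identifiable*: `k_on_csk` and `k_off_csk_uu`
enter the observable kinetics almost only through their ratio (the CSK
dissociation constant), so freeing both would leave a ridge along which
they drift together by many decades; freezing `k_on_csk` pins the Kd and
makes `k_off_csk_uu` recoverable. Under this design the two-stage fit
recovers all six log10 parameters within ±0.5 dex (typically ±0.1) and
beats truth-plus-noise on the quantitative objective.

## Ensemble selection, clustering and statistics

`select_ensemble()` applies, in order: a training-WSSR cutoff, a
validation-WSSR cutoff (each survivor is re-simulated through the dead-LCK
model against the validation data), and removal of sets in which less than
90% of the LCK is doubly phosphorylated at 90 min in the high-LCK condition
— a molecularly detailed feature of the experiments. The published cutoffs
(7.1 and 3.3) were read visually off CDF plots, which is not reproducible;
they ship as fixed defaults, with an automated alternative
(`cdf_mode = "elbow"`) that places the cutoff at the largest second
difference of the sorted log10-WSSR curve, halfway between the last set of
the low-WSSR step and the first set beyond it. Every removal is attributed
to the criterion that caused it, and the filter is idempotent.

`cluster_parameter_sets()` runs k-means on standardized log10 parameters
(raw-scale distances would be dominated by the fastest rates; constant
columns are dropped), selecting k ∈ 2…6 by the maximal sum of silhouette
widths; identical inputs return a single cluster with a diagnostic.
`ensemble_stats()` reports per-parameter medians with 90% CIs (5th–95th
percentile) and one-way ANOVA comparing log10 rates across the four enzyme
forms on each common substrate site; when the sets are identical there is
no sampling variability and the p-values are reported as `NA` rather than
claiming significance.

## Sensitivity analysis

`efast()` implements the extended Fourier amplitude sensitivity test: all
inputs vary together along the search curve x = ½ + asin(sin(ωs + φ))/π,
the driven parameter at ω_max = ⌊(Ns−1)/2M⌋ and the complementary set
cycling through 1…⌊ω_max/2M⌋; first-order indices take the spectral power
at the driver's first M harmonics, total indices are one minus the power
below ω_max/2. Defaults M = 4 and Ns = 65 per curve are the customary
minimum. Variances are pooled across resample curves (random phases) before
the ratios are formed — per-curve ratios are strongly phase-dependent when
complementary frequencies are commensurate — and a dummy parameter
estimates the significance floor. The implementation reproduces the
analytic Ishigami indices within 0.05 (Ns = 257, 16 resample curves).

`efast_lck()` varies all 38 rates 100-fold up and down from the medians
(log-uniform: a multiplicative range implies log-scale exploration) and
records total phospho-Y394 and phospho-Y505 as fractions of total LCK, by
default at 90 min (the analysis times were described only as "specific time
points"; any grid can be supplied). At the medians the top-ranked total
indices are the two shared association rates and the CSK–U394U505
dissociation and catalytic rates — the same parameters whose fitted
distributions are narrow — while most of the remaining 34 parameters sit
near the dummy's floor. `compare_conditions()` quantifies ranking
concordance across conditions by Spearman correlation of the total indices.

## Numerical choices and limitations

* Swarm and refinement searches work in log10 space throughout; bounds are
  hard (positions clipped, wall-normal velocity zeroed).
* The near-optimum "ensemble envelope" robustness check uses sets jittered
  ±0.25 dex around the medians: resampling parameters *independently*
  within their 90% CIs destroys the correlations of the fitted ensemble and
  pushes the median curve outside the resampled band, so it is not a valid
  surrogate for the published correlated ensemble.
* Problem sizes in the shipped tests are desk-scale by design: 3-run
  campaigns, 65–257 samples per eFAST curve, 500-replicate noise Monte
  Carlo. Passing them demonstrates correctness of the machinery on data
  whose generating process is known exactly — not that real blot data are
  this well behaved (they carry digitization error, correlated noise and
  an uncertain initial phospho-Y505 fraction).
* The exact membership of the published 33-set and 20-set ensembles is not
  reproducible at this scale (it depends on a 1000-run stochastic campaign
  against figure-digitized data); what is reproducible — and tested — is
  the behavior of each stage on known-truth synthetic campaigns.
* In-solution (3-D) kinetics are out of scope: the mechanism fitted here
  describes the membrane system, and the published attempt to transfer it
  to solution data failed even with all rates free.
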