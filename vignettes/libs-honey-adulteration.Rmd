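---
title: "Quantifying honey adulteration from LIBS spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying honey adulteration from LIBS spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Honey is commonly adulterated either with sugar syrups — high-fructose corn
syrup (HFCS) F55 or F90 — or with cheaper honeys such as rape honey.
Laser-induced breakdown spectroscopy (LIBS) ablates a microscopic amount of
sample and records atomic emission from the plasma, so it sees the
*elemental* fingerprint of the sample: C, H, O, N and the CN molecular band
from the sugar matrix, and the mineral lines (Mg, Ca, Na, K) that
distinguish honey from syrup.  `libsquant` implements the full chemometric
workflow that turns such spectra into a quantitative estimate of the
adulterant mass fraction: peak-variable extraction over a fixed 43-line
emission library, autoscaled SIMPLS partial least squares regression (PLSR)
with 10-fold cross-validation, a univariate screen, and three feature
selection schemes (GA, VIP, SR).

Because no public spectra exist for this task, the package ships a
synthetic-spectrum generator that emulates the study design: binary
mixtures of acacia honey with one adulterant at 21 calibration levels
(0–100 % in 5 % steps) and 13 external prediction levels (0–96 % in 8 %
steps), three replicates each — 63 calibration and 39 prediction samples
per adulterant series.

## The simulator

### Endmember profiles

Each of the four endmembers (acacia honey, rape honey, HFCS F55, HFCS F90)
is a vector of 43 non-negative line amplitudes.  An amplitude is the
product of two factors:

* a **group abundance level** — fixed numbers per element group and
  endmember (see `endmember_config()`), encoding the qualitative contrasts
  of these materials: Mg, Ca and K present only in the honeys; Na roughly
  three-fold stronger in acacia than in rape honey and near-absent in the
  syrups; C/H/O/N/CN present everywhere, strongest in the carbon-rich F90
  syrup; Si and the four unidentified lines constant background shared by
  all endmembers;
* a **per-line emission strength**, drawn once per seed as
  U(1 − jitter, 1 + jitter) with jitter = 0.1 and *shared by all four
  endmembers*.  This factor stands for the transition strength of the line
  itself, which is a property of the emission, not of the sample.  A
  useful consequence is that every line of a binary mixture varies through
  a single linear abundance term, so noiseless peak variables are exactly
  affine in the mixing fraction — the property the parameter-recovery
  tests rely on.

Mixing is linear in the mass fraction:
`amp(f) = (1 − f) · amp_pure + f · amp_adulterant`.

### Rendering and noise

Profiles are rendered as Gaussian peaks (default FWHM 0.30 nm, chosen to
resolve the Na doublet at 589.03/589.64 nm) on a uniform 0.05 nm grid over
240–860 nm (12,401 points) above a constant baseline (default 1 a.u.).
There is no wavelength-dependent continuum: the downstream variable is the
raw observed peak intensity, so baseline realism is secondary.

Measurement noise follows the shot-averaging protocol: each of `n_shots`
(default 100) copies of the spectrum receives independent N(0, `sigma_shot`)
noise at every pixel and the copies are averaged, leaving pixel noise of
`sigma_shot / sqrt(n_shots)`.  Negative averaged intensities are clipped to
zero *after* averaging (physical non-negativity).  The default
`sigma_shot = 5` puts roughly 0.5 intensity units of noise against mineral
peak amplitudes of 7–36, which yields univariate correlations in the high
0.9s for mineral lines and near zero for the constant background lines — a
clean but not trivial regime.

**What the simulator does not emulate:** plasma physics (no Saha–Boltzmann
populations, no self-absorption), matrix effects beyond linear mixing,
wavelength drift, and any continuum emission.  Passing tests on this
generator therefore demonstrate the correctness of the chemometric
machinery and its behaviour under controlled noise — not instrument-level
performance on real honey spectra, whose error levels are set by effects
outside this model.

## Peak extraction

The regression variable for a line is the maximum intensity over grid
points within ±0.25 nm of its nominal wavelength — no baseline
subtraction, no line fitting.  The half window separates the Na doublet
(0.61 nm apart) while tolerating a few grid steps of position mismatch.
Max-in-window keeps the variable definition assumption-free; the cost is a
small upward noise bias (the maximum of ~10 noisy values), which the
multivariate models absorb.  The original study does not state its
integration window or background treatment, so these two choices are
package decisions, not reproductions.

## The regression machinery

### Autoscaling

Predictors are mean-centred and divided by their per-column standard
deviation (n − 1 denominator, the chemometric convention).  The response is
centred but not variance-scaled — with a single response the regression
slope absorbs its scale.  Zero-variance columns cannot be autoscaled;
`autoscale_fit()` rejects them by name.  Model-fitting wrappers drop
*near*-constant columns beforehand (SD below 1e−10 of the column's
magnitude): noiseless simulations leave ~1e−16 of mixing round-off on
lines shared by both endmembers, and autoscaling such a column would
amplify pure floating-point residue into a full-scale junk variable.

### SIMPLS

`simpls_fit()` implements de Jong's SIMPLS for a single response: the
cross-product s = Xᵀy is repeatedly projected off the orthonormalized
X-loading basis; each deflated s is the next weight vector, scores are
normalized to unit length, and the regression vector is b = R q.  Scores
are mutually orthogonal by construction, and for one response SIMPLS is
equivalent to NIPALS PLS1 — the test suite verifies both properties
against an independently coded NIPALS oracle, and checks that using all
p factors reproduces the ordinary least-squares fit.  Factor extraction
stops (with an informative error) when the deflated cross-product or the
score norm falls below 1e−10 of its initial magnitude, which is how exact
low-rank data (noiseless mixtures are rank one after centring) is
detected.

### Cross-validation

`kfold_cv()` assigns samples to 10 random folds (seeded), refits the model
*including its autoscaling* on each training fold (no leakage), and scores
every factor count 1..A_max on the held-out samples.  A_max defaults to 10
and is capped at the rank achievable in every training fold, with a
warning.  The chosen factor count is the smallest one whose RMSECV is
within a factor 1 + 1e−8 (plus 1e−12 absolute) of the minimum: a pure
argmin is undefined to rounding error on exact-rank-1 data, and resolving
ties toward fewer factors is the overfitting-averse reading of
"cross-validation determines the number of latent variables".

## Feature selection

* **VIP** accumulates squared normalized PLS weights over factors, each
  weighted by the response variance that factor explains; the scores
  satisfy Σⱼ VIPⱼ² = p exactly (asserted at 1e−10 in the tests), which
  grounds the classical VIP > 1 selection rule.
* **SR** (selectivity ratio) projects the scaled predictor matrix onto the
  normalized regression vector (target projection) and scores each
  variable by explained over residual squared norm.  The threshold is the
  upper-0.05 quantile of F(n − 2, n − 3); at the 63-sample calibration
  design this is 1.532, matching the conventional printed cutoff.  These
  degrees of freedom were chosen precisely because they reproduce that
  published value at n = 63.  A variable with zero residual (a perfect
  predictor) scores +Inf with a warning and sorts above any threshold.
* **GA** runs a binary-chromosome genetic algorithm: fitness is the
  negative RMSECV of a SIMPLS model on the chromosome's variables (inner
  5-fold CV, folds fixed within a run so fitness values are comparable;
  the factor count is re-chosen by that same CV).  Tournament selection,
  single-point crossover (p = 0.5), bit-flip mutation (p = 0.01) and
  elitism of 1; the all-zero chromosome receives −Inf.  Five independent
  runs are aggregated: the final mask keeps variables present in ≥ 60 % of
  the runs' best chromosomes.  The source study names GA but none of its
  hyperparameters, so these defaults follow common small-p GA-PLS practice
  and are fully configurable.

VIP and SR are computed from the full-variable model at its CV-chosen
factor count (the study leaves this unstated; scoring the deployed model
is the natural reading).  After any selection, the reduced model's factor
count is re-chosen by a fresh cross-validation — reduced models may
legitimately use a different number of latent variables than the full one.

## The orchestrated study

`run_study()` executes, per adulterant: simulate → extract → univariate
screen → full PLSR → GA-/VIP-/SR-PLSR, producing 12 evaluation reports
(3 adulterants × 4 methods) with r and RMSE for calibration,
cross-validation and prediction, plus per-sample predicted-vs-actual pairs
for scatter plots.  All randomness derives from one master seed through a
fixed counter scheme (100 child seeds reserved per adulterant branch;
within a branch: dataset, CV folds, GA, and one seed per reduced model),
so adding a method never shifts another branch's draws and reruns are
byte-identical.  RMSEs are stored as fractions and rendered as percentages
with one decimal in summaries.

## Numerical and design choices, in brief

* Peak shape Gaussian, FWHM 0.30 nm; grid 0.05 nm over 240–860 nm;
  baseline 1 a.u. — echelle-like resolution, desk-scale memory.
* Clipping at zero applied after shot averaging.
* Autoscale SD uses n − 1; response centred only.
* CV ties resolve to the smallest factor count (tolerance 1 + 1e−8).
* Near-constant columns (SD < 1e−10 × magnitude) are excluded from
  modelling and flagged `constant` in the univariate screen.
* SR degrees of freedom (n − 2, n − 3); infinite SR sorts above any
  threshold.
* CSV artifacts are written with 17 significant digits, which round-trips
  IEEE doubles exactly and keeps writers byte-deterministic.

## Problem sizes used by the test suite

The oracle equivalences run on 50 random 25 × 7 instances (SIMPLS vs
NIPALS), a 30 × 8 full-rank instance (OLS limit), a 6-sample toy
(leave-one-out vs brute force), and 30 × 10 instances (SR projection
oracle).  Parameter recovery uses the full default design: one noiseless
run for exact recovery and a 3-level noise ladder (sigma_shot 1, 5, 25)
averaged over 10 seeds for monotonicity.  Selection recovery runs 10 seeds
of a designated-contrast dataset in which only the ten mineral lines
differ between endmembers, and a 40 × 10 planted-predictor instance for
the GA.  These sizes keep the default suite around five minutes on one
core while leaving the statistical margins of the 9-of-10 criteria wide.

## Known limitations

* The simulator's amplitude levels are free parameters of this package,
  not calibrated to any instrument; published per-line correlations and
  RMSEs from real honey studies are therefore illustrative context, not
  reproduction targets.
* Max-in-window extraction biases intensities upward under noise and
  partially blends lines closer than the window (e.g. the N I pair at
  818.57/818.86 nm); a line-fitting extractor would decouple them at the
  cost of shape assumptions.
* Single-response PLS1 only — no PLS2, no OPLS, no outlier diagnostics.
* The GA is stochastic by nature; only its seeded reproducibility and its
  behaviour on planted signals are guaranteed by tests, not the optimality
  of any particular subset.
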