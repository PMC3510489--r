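---
title: "Detecting and modelling two-state polymorphism in B-DNA helical parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling two-state polymorphism in B-DNA helical parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helibimod)
```

## The statistical model

The elastic picture of DNA flexibility assumes that each inter-base-pair
helical parameter $x$ of a dinucleotide step fluctuates around one
equilibrium value with a Gaussian distribution; equivalently, the
deformation energy is harmonic, $E = \tfrac12 K\,\Delta X^2$ with
$K = k_BT/\sigma^2$. The question this package answers, ensemble by
ensemble, is whether that single-Gaussian description holds, or whether the
data demand the binormal model

$$g(x) = p_r\, f_1(x) + (1-p_r)\, f_2(x), \qquad
  f_c = \mathcal N(\mu_c, \sigma_c^2),$$

and, if they do, whether the two components are separated enough for the
density itself to have two modes — the signature of a genuine
conformational polymorphism rather than mere non-Gaussian broadening.

### Model selection: BIC and the Bayes-factor posterior

Both models are fitted by maximum likelihood (the Gaussian in closed form
with the $n$-divisor variance; the mixture by EM, below) and compared with
the Bayesian Information Criterion $\mathrm{BIC} = -2\ln L + k\ln n$, with
$k=2$ and $k=5$ free parameters respectively; the lower BIC wins. At most
two components are ever fitted: with the sparse ensembles that occur for
some step/origin combinations, more components invite over-fitting.

The BIC difference approximates $-2$ times the log Bayes factor between the
models. With equal prior weight on one and two components,

$$p(M_2\,|\,\mathrm{data}) = \frac{F}{1+F}, \qquad
  F = e^{(\mathrm{BIC}_1-\mathrm{BIC}_2)/2},$$

computed in log space (`plogis`) so that extreme BIC differences cannot
overflow. Evidence labels use strict thresholds: **M2** when
$p > 0.95$, **M1** when $p < 0.05$, **IE** (insufficient evidence)
otherwise — the boundary values themselves are IE. No multiple-testing
correction is applied across the classification grid: each cell is an
independent decision at fixed thresholds, and the report states so.

### The EM fit and its safeguards

`fit_binormal()` runs EM from several deterministic initializations: a
median split with half-sample moments, the degenerate single-Gaussian
configuration, and (by default) four seeded random perturbations of the
quartile means. The degenerate start makes the nesting property
$\ln L_2 \ge \ln L_1$ a theorem rather than a hope: EM never decreases the
likelihood, and that start already achieves the single-Gaussian likelihood.
Numerical safeguards, all standard for univariate mixtures:

* **σ floor** at $10^{-3}\times$ the sample SD — without it the likelihood
  is unbounded as a component collapses onto one data point;
* **$p_r$ clamped** to $[10^{-3}, 1-10^{-3}]$;
* convergence when the log-likelihood improves by less than $10^{-8}$, cap
  of 500 iterations; a non-converged best fit is returned but flagged;
* components reported in ascending-mean order, removing label switching;
* an optional `fit_range` restricts the sample to an interval before
  fitting, for ensembles where a neighbouring basin must be excluded.

The tests cross-check the EM against a brute-force lattice search on tiny
samples and against an independent mixture implementation (mclust) at tight
tolerance; per-iteration monotonicity of the likelihood is asserted
directly.

### Modality: the generalized Helguero criterion

A two-component fit is not automatically bimodal. With
$r = \max(\sigma_1^2,\sigma_2^2)/\min(\sigma_1^2,\sigma_2^2) \ge 1$ and

$$S(r) = \frac{\sqrt{-2+3r+3r^2-2r^3+2(r^2-r+1)^{3/2}}}{\sqrt r\,(1+\sqrt r)},$$

the mixture density is unimodal for *every* mixture proportion if and only
if $|\mu_2-\mu_1| \le S(r)(\sigma_1+\sigma_2)$. At $r=1$ this reduces to
the classical bound of two standard deviations between the means. The
implementation defines $r\ge1$ so one branch of the formula suffices; a
symmetry test enforces invariance under swapping the components.

Because the criterion quantifies over all proportions, its independent
oracle needs care. `bimodal_p_range()` solves the stationarity condition
$p/(1-p) = -f_2'(x)/f_1'(x)$ between the means: the proportion-vs-location
curve runs from 1 to 0, and the density has two modes exactly for
proportions strictly between its interior turning points; a monotone curve
means no proportion is bimodal. `count_modes_numeric()` counts grid maxima
of the density (4096 points over $\pm6\sigma$). The test suite sweeps 2500
random (separation, σ-ratio) configurations and requires that the analytic
label never contradicts these oracles — for a **B** label, two modes must
actually appear at a proportion inside the computed interval; for **U**, no
interval may exist. A bimodal label at the threshold boundary flips exactly
where the oracle's interval appears (bisection test).

M2/U cells — binormal but effectively unimodal — are summarized by the
exact mixture moments (`weighted_stats()`): mean
$p_r\mu_1+(1-p_r)\mu_2$ and the corresponding mixture variance.

### Pipeline gating

Modality is evaluated only for M2 cells; M1 cells are U by definition
(label `M1/U`), and IE cells receive no modality call. The grid therefore
contains the four categories `M1/U`, `M2/U`, `M2/B`, `IE`, plus a `status`
column: per-cell failures (too few records, zero variance) are recorded in
place and never abort the remaining cells.

## The two-state elastic model

For a parameter classified M2/B, one harmonic well is wrong in a specific,
quantifiable way: the unimodal equilibrium value sits near the *barrier*
between the substates, and the unimodal σ — inflated by the two-state
spread — understates the stiffness of either well.
`unimodal_error_profile()` tabulates exactly this error.

The refined model keeps one harmonic state per substate. Snapshots are
assigned to components by posterior responsibility (hard 0.5 threshold,
ties to the lower-mean state — the simplest deterministic reading of
"use the fit to define each snapshot's reference state"), and each part
yields its own $\mathbf{x}_0$ and stiffness matrix
$K = k_BT\,\Sigma^{-1}$, diagonal and off-diagonal elements alike. The
free-energy offset between the substates comes from Boltzmann inversion of
the fitted populations, $\Delta G_{ij} = k_BT\ln(p_{\rm major}/p_{\rm
minor}) \ge 0$ — the only estimator available from the fit itself. The two
branches

$$E_i = \tfrac12\,\Delta X_i^{\mathsf T} K_i\,\Delta X_i, \qquad
  E_j = \tfrac12\,\Delta X_j^{\mathsf T} K_j\,\Delta X_j + \Delta G_{ij}$$

combine either as the discontinuous minimum $\min(E_i, E_j)$ (fine for
single-point energies, unusable for optimization or dynamics because of the
derivative jump at the crossing) or through the smooth two-state coupling,
the lower eigenvalue of the secular matrix
$\begin{pmatrix}E_i & \varepsilon\\ \varepsilon & E_j\end{pmatrix}$:

$$E = \tfrac12(E_i+E_j) - \tfrac12\sqrt{(E_i-E_j)^2 + 4\varepsilon^2}.$$

This is everywhere $\le \min(E_i,E_j)$, deeper by exactly $\varepsilon$ at
a crossing and by a vanishing amount far from it, and has continuous first
derivatives. The default $\varepsilon = 0.25\,k_BT$ is a compromise: small
enough that barrier shapes are preserved (the depression is at most a
quarter $k_BT$), large enough that gradients vary smoothly on the scale of
thermal fluctuations. It is configurable wherever it appears.

When $n$ parameters of one step are bimodal, the bookkeeping grows as
$2^{n-1}$ state models (`n_state_models()`); the package enforces the count
but deliberately stops short of fitting multi-parameter couplings — with
one bimodal coordinate per step being the empirically dominant case, the
cross-terms are left to the per-state stiffness matrices.

## Kinetics of two-state transitions

For MD-like time series, `assign_states()` performs hard frame-wise
assignment by posterior responsibility (recording, for reference, the
boundary where the weighted component densities cross between the means).
No hidden-Markov smoothing is applied: the intent is the direct
threshold reading of a twist trace. The consequence is that emission noise
near the boundary produces spurious one-frame recrossings; the optional
`min_dwell_frames` filter (default off) merges dwells shorter than a given
number of frames back into their surroundings. With overlapping states a
few frames of minimum dwell remove essentially all noise flips while
biasing true dwell lengths only at the fraction-of-a-percent level; the
kinetics tests use 2–5 frames at 1 ps spacing.

`transition_stats()` counts every state change (both directions) and
reports transitions/ns, per-state occupancies, and mean residence times
over *completed* dwells — the censored first and last dwells are excluded,
which is what makes the estimator unbiased. `convergence_profile()`
recomputes occupancy and rate on growing prefix windows (the standard
demonstration that a short trajectory overestimates its initial substate's
population) and on consecutive equal blocks, reporting the largest relative
deviation of a block rate from the mean — the check that the transition
frequency is stationary along the trajectory.

## Synthetic data: what it emulates and what it does not

The generators produce exactly the structures the analysis assumes:

* `sample_binormal()` — i.i.d. draws from a binormal spec
  (Bernoulli component choice, Gaussian emission);
* `sample_telegraph()` — a discrete-time two-state Markov chain with
  per-frame switch probabilities $1-e^{-k\,dt}$ (exact exponential
  holding times in the continuum limit) and Gaussian per-state emissions,
  returning the hidden state sequence alongside the observations so
  estimator recovery can be scored against ground truth. A warning is
  issued when $dt(k_{12}+k_{21}) > 0.2$, where discretization error becomes
  material;
* `sample_harmonic()` — multivariate Gaussian snapshots with covariance
  $k_BT\,K^{-1}$, the exact stationary distribution of the harmonic model.

The scenario presets place the CpG low-twist mode at 25° and the ApG/CpC
minor slide mode at −1.5 Å — the two well-established polymorphisms —
while all other preset numbers (major modes, widths, weights) are plausible
round values, not measurements. What the synthetic data deliberately lacks:
autocorrelation within a state (MD frames are correlated; here emissions
are i.i.d. given the state), skewness and heavy tails, BI/BII backbone
coupling, and any sequence-context dependence. Passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions, not force-field realism.

Angles are treated as plain reals in degrees throughout: B-DNA fluctuations
span far less than 360°, so circular statistics would add nothing.

## Numerical and design choices

* **Curation.** The anomalous-step filter removes records more than
  $k$ SD (default 3) from the ensemble mean, with mean and SD computed
  once on the input — a single pass, never iterated. It is applied
  per parameter (the downstream analysis is univariate) and, by default,
  only to X-ray origins; whether simulation ensembles should receive the
  same filter is genuinely open, so it is a switch, not an assertion.
  Subsampling to a fixed size per step is seeded and clamped; a stability
  report can compare two seeds.
* **BIC convention.** $-2\ln L + k\ln n$, minimized — the convention under
  which "the model with the lower BIC is chosen" is true.
* **$k=2$ and $k=5$.** Free parameters are exactly $\{\mu,\sigma\}$ and
  $\{\mu_1,\sigma_1,\mu_2,\sigma_2,p_r\}$.
* **Boundary posteriors.** $p(M_2|\mathrm{data})$ of exactly 0.95 or 0.05
  classifies IE (strict inequalities).
* **Determinism.** Every stochastic operation takes an explicit seed and
  restores the caller's RNG state; `run_config()` with the same config
  twice produces byte-identical numeric output (reports print numerics at
  6 significant digits).
* **Problem sizes in the tests.** Threshold-attainment and recovery checks
  use $n = 10^4$ samples (10–20 seeds), the stiffness round trip
  $n = 10^5$ snapshots, the kinetics recovery a 1000 ns series at 1 ps
  frames ($10^6$ frames, ~5000 dwells), and the modality sweep 2500
  configurations — sizes at which the Monte-Carlo error sits comfortably
  inside each stated tolerance (e.g. dwell-time SE ≈ 2% against a 5%
  bound).
* **Recovery tolerances.** "Within 5% of truth" is evaluated as
  $|{\rm est}-{\rm truth}| \le 0.05\max(|{\rm truth}|, 1)$, i.e. an
  absolute 0.05 for a true value of 0 — a relative bound at zero is
  meaningless.

## Known limitations

* The Bayes-factor posterior inherits the BIC approximation (implicitly a
  unit-information prior); no exact marginal likelihoods are computed.
* Mixtures of three or more components are never fitted, even where a third
  component might improve the fit.
* The modality criterion applies to the *fitted* binormal model; it is not
  a nonparametric bimodality test (no dip test, no kernel-density mode
  counting of raw data).
* Stiffness estimation assumes an equilibrated, effectively independent
  sample; correlated MD frames make the effective $n$ smaller than the
  frame count, and no autocorrelation correction is applied.
* The energy model supports evaluation only — no geometry optimization or
  dynamics on the surface.
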