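---
title: "Bimanual coordination scoring and path-analytic connectivity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimanual coordination scoring and path-analytic connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimansem)
```

## What this package models

`bimansem` implements a complete analysis chain for a classic
motor-control paradigm: visually paced bimanual finger tapping in a
stable *in-phase* mode (mirror-symmetric: both index fingers, then both
middle fingers) and a harder *anti-phase* mode (parallel: left middle
with right index, alternating with left index and right middle), tested
at several pacing frequencies in two age groups. The chain runs from
button-press scoring, through a minimal first-level GLM on ROI-averaged
BOLD signals, to maximum-likelihood path analysis (observed-variable
structural equation modelling, SEM) of ten bilateral motor-association
regions: M1, S1, PMd, SMA and SPL, left and right.

Because raw data of this kind are rarely public, the package ships a
first-class synthetic-data module with known ground truth for every
stage, so each statistical claim the pipeline makes can be tested
against the generating parameters.

## Task structure and behavioral scoring

A run alternates 20 s rest and 20 s task blocks (9 rest + 8 task
blocks, 340 s in total) with the coupling mode alternating across task
blocks; volumes are acquired every `tr_s = 3` s, and the default 113
volumes cover 339 s, the last partial volume never being acquired.
Within a task block, one pacing cycle is one alternation of the cue
pair, so cue onsets fall at $k/f$ seconds after block onset for pacing
frequency $f \in \{1.0, 1.5, 2.0\}$ Hz.

A press is judged by latency differences to the *opposite* hand: with
$d_{\text{same}}$ the smallest absolute time difference to the
opposite hand's same finger and $d_{\text{diff}}$ that to its other
finger, an in-phase press is correct iff
$d_{\text{same}} < d_{\text{diff}}$, an anti-phase press iff
$d_{\text{diff}} < d_{\text{same}}$. The accuracy rate is correct
presses over all presses. Three aspects are under-determined by that
rule and are explicit configuration:

* **Matching window** (`match_window_s`): only opposite-hand presses
  within this window are candidates. Default: half the pacing period,
  so a press can only pair with its own cycle.
* **Ties** (`tie_policy`): exact equality of the two distances counts
  as incorrect by default (conservative; ties have measure zero in
  real, jittered data).
* **Unmatched presses** (`unmatched_policy`): a press with no
  opposite-hand candidate counts as incorrect by default, because a
  movement without a bimanual counterpart cannot be a correct bimanual
  movement. Spurious extra presses therefore deflate accuracy through
  the denominator; excluding them instead is a policy switch.

Each press is classified independently; no cycle segmentation is
needed. Two exact symmetries are used as tests: accuracy is invariant
under a global time shift, and relabelling one hand's fingers maps
in-phase-correct presses onto anti-phase-correct ones and vice versa.

The pacing frequency taken forward to connectivity analysis maximizes
the young-minus-elderly difference in mean anti-phase accuracy,
subject to the young group staying at or above a floor (default 0.8)
so the task remains manageable for them; ties break toward the lower
frequency.

## The behavior generator

`simulate_presses()` emulates a participant with four knobs:
Gaussian press-time jitter (`timing_sd_s`, seconds), a per-cycle
probability of slipping into the mirror pattern (`swap_prob`, the
signature of a phase transition from anti-phase toward in-phase
coordination — the slip is modelled as the left hand striking the
other finger), a per-press omission probability (`miss_prob`) and a
per-cycle spurious-press probability (`extra_prob`). In the
noiseless-timing limit the scored accuracy equals $1 -$ `swap_prob`
exactly in expectation, which gives a binomial oracle for the scorer.

The default pipeline profiles place the group-level mean accuracies in
the canonical qualitative pattern — young anti-phase accuracy high at
1.0 and 1.5 Hz collapsing at 2.0 Hz, elderly anti-phase accuracy low
throughout, both groups accurate in-phase — with small miss/extra
rates (2% young, 5% elderly) and 50–80 ms timing jitter as plausible
motor-output values. These are fixed study conditions of the
simulation, not tuning knobs.

What the generator does *not* emulate: within-subject learning or
fatigue, auditory–visual cue latency, correlated errors across
neighbouring cycles, and hand dominance asymmetries in timing.
Passing tests therefore validate the scoring and selection logic, not
the realism of any particular participant model.

## BOLD generation and the first-level GLM

Each ROI's series is a sum over modes of an amplitude times the mode's
block boxcar convolved with a canonical double-gamma haemodynamic
response (peak 6 s, undershoot 16 s, undershoot ratio 1/6), sampled at
the TR, plus AR(1) Gaussian noise (default autocorrelation 0.2,
marginal SD configurable). The design matrix contains, per mode, the
convolved boxcar and its temporal derivative (finite difference),
plus an intercept and a linear polynomial drift (order configurable).
The same convolution code serves generator and design, so noiseless
recovery is exact by construction and is asserted at `1e-8`.

Estimation is ordinary least squares; the "beta" passed to SEM is the
task-versus-rest contrast of the HRF column only, the derivative being
a nuisance column (a switch `include_derivative` exposes the
amplitude-weighted combination instead). There is no autocorrelation
prewhitening: under AR(1) noise the OLS standard errors are somewhat
anticonservative, a known limitation; the confidence-interval
calibration test therefore runs under the estimator's own white-noise
assumption, where coverage of `beta +/- 1.96 se` sits in the nominal
93–97% band over 200 simulated subjects.

## The SEM engine

Observations are modelled as a linear structural system
$x = Ax + \zeta$ over the $p$ observed variables, with $A$ the matrix
of free directed path coefficients (zero diagonal) and
$\zeta \sim N(0, \Psi)$ disturbances, $\Psi$ diagonal by default
(free disturbance covariances are supported but off, since none are
reported in the motivating analyses). The implied covariance is

$$\Sigma(\theta) = (I - A)^{-1} \Psi (I - A)^{-\top},$$

and fitting minimizes the maximum-likelihood discrepancy

$$F(\theta) = \log\lvert\Sigma\rvert + \operatorname{tr}(S\Sigma^{-1})
  - \log\lvert S\rvert - p,$$

with $S$ the sample covariance on denominator $N-1$. $F$ equals twice
the Kullback–Leibler divergence between the centred Gaussians — an
identity used as an independent oracle in the tests. The chi-square
statistic is $(N-1)\,F_{\min}$ on $p(p+1)/2 - t$ degrees of freedom
for $t$ free parameters, matching the convention of the commercial
SEM software this engine mirrors.

**Optimization.** Quasi-Newton (BFGS) on an unconstrained
parameterization (log disturbance variances) with analytic gradients;
starting values are per-equation least-squares regressions computed
from $S$ alone. Convergence requires gradient infinity-norm below
`1e-6` and discrepancy change below `1e-10`; up to ten BFGS restarts
are run, and on failure three deterministic alternative starts shrink
the regression coefficients toward a diagonal model. Reciprocal
(nonrecursive) path pairs are allowed; stability is checked via the
spectral radius of $\hat A$ with a warning when it reaches 1.

**Standard errors and standardization.** The observed information of
$\tfrac{N-1}{2} F$ at the solution (central finite differences of the
analytic gradient) is inverted for standard errors; a rank-deficient
information matrix triggers an "empirically unidentified" warning
naming the flattest parameter directions. Standardized coefficients
are $\beta_{ij} = \hat a_{ij}\,\hat\sigma_j/\hat\sigma_i$ with fitted
standard deviations, verified against a refit on correlation-scaled
data. Two-sided normal p-values per path feed the three display tiers
(`p<0.001`, `p<0.01`, `ns` at `p >= 0.01`).

**Fit battery.** GFI
$= 1 - \operatorname{tr}[(\Sigma^{-1}S - I)^2] /
\operatorname{tr}[(\Sigma^{-1}S)^2]$; CFI against the independence
baseline (free variances only, whose ML solution is closed-form);
RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$, undefined at
$df = 0$; chi-square-based AIC $= \chi^2 + 2t$ and BIC
$= \chi^2 + t\log N$, documented as differences-only quantities. The
conventional acceptance battery is chi-square $p > 0.05$, GFI and CFI
above 0.95, RMSEA below 0.05.

**Specification search.** A greedy hill-climb over single-edge
additions, deletions and reversals, accepting the move that most
improves AIC (or BIC), stopping when no move improves or the
acceptance battery is already met; ties break toward fewer parameters,
then lexicographic edge order. Candidate edges can be restricted. The
full evaluated-move trace is returned. One caveat the tests respect:
directed path models come in covariance-equivalence classes, so when a
deleted edge points into a near-sink variable, equivalent
re-orientations can tie with the true restoration on AIC and the
search may legitimately pick either; the single-edge recovery test
deletes a premotor-to-motor path whose restoration is unique.

## Synthetic connectivity ground truths

Four bundled `connectivity_fixture()` models (age group x mode) over
the ten ROIs each carry 26 directed paths (36 free parameters, 19 df).
Their strong-path sets (coefficients 0.4–0.6, unit disturbances)
differ across conditions in the qualitative pattern expected of young
versus elderly coordination networks (reciprocal bilateral PMd
coupling and left-to-right drive in young; right-to-left
interhemispheric drive and an intra-left PMd→M1→S1 chain in elderly),
with weak filler paths (0.05–0.25) completing the topology. All
coefficients are synthetic design choices: they reproduce a *pattern*
of tiered significance, not any estimated values.

## Problem sizes, calibration, and small-N reality

The test and acceptance workloads use sizes at which each property is
statistically decidable: Monte-Carlo covariance convergence at
$n = 10^6$ (sup-norm < 0.01), parameter recovery over 100 replicates
at $n = 5000$ (mean absolute bias < 0.02, CI coverage 92–98%),
chi-square calibration over 1000 replicates at $n = 500$ (mean within
5% of df), and 20-seed single-edge search recovery at $n = 5000$.

The canonical study regime — $N = 20$ subjects per group against
$t = 36$ free parameters — deserves honesty: there the ML chi-square
is substantially inflated in finite samples (its mean sits around
26 rather than df = 19 in our simulations), so RMSEA < 0.05 regularly
fails *even for the true topology*, and roughly half of fits end in
improper solutions (a disturbance variance diverging with compensating
coefficients, the Heywood-type ridge familiar from small-sample SEM).
`fit_ml()` emits an explicit low-N reliability warning in this regime
rather than refusing, flags improper solutions, and the pipeline
compares path tiers only across converged fits, reporting any
exclusions. Published fit statistics obtained in such regimes after a
specification search should be read with this selection effect in
mind; the pipeline makes the phenomenon reproducible instead of hiding
it.

## Known limitations

* OLS GLM without prewhitening: anticonservative under autocorrelated
  noise (documented above).
* The SEM engine handles observed variables only — no latent
  measurement models, no multi-group equality constraints, no
  Bayesian estimation.
* Greedy search explores one move at a time and cannot distinguish
  covariance-equivalent models; it returns *a* best-fitting topology,
  not a causal identification.
* Group comparison is deliberately tier-based (strong in one
  condition, absent/non-significant in another); raw coefficients are
  never compared across different topologies.
* The accuracy pipeline reports descriptive means and t-based 95%
  CIs; inferential ANOVA machinery is left to standard packages.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
report <- run_pipeline(cfg, out_dir = "pipeline_out")
print(report)

# the SEM engine stand-alone
truth <- connectivity_fixture("young", "anti_phase")
x <- simulate_roi_observations(truth, 500, seed = 2)
fit <- fit_ml(as_path_model(truth), sample_moments(x))
print(fit)
classify_path_tiers(fit)
```
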