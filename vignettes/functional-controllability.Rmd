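---
title: "Functional controllability of fMRI connectomes: methods and design"
author: "funcontrol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional controllability of fMRI connectomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcontrol)
```

## The model

The package treats brain activity as a discrete-time linear dynamical system

$$x(t+1) = A\,x(t) + B\,u(t),$$

where $x$ is the vector of ROI BOLD signals, $A$ is a connectome estimated
from the same functional data, $u$ is an arbitrary input, and $B$ selects
where the input enters. Two node-level quantities summarize how inputs
propagate through this system:

* **Average controllability** of ROI $i$ is the trace of the
  infinite-horizon controllability Gramian for the single-input system
  $B = e_i$, i.e. the solution of the discrete Lyapunov equation
  $W_i = A W_i A^\top + e_i e_i^\top$. For symmetric $A$ with
  eigendecomposition $A = V \Lambda V^\top$ this is
  $\sum_j v_{ij}^2 / (1-\lambda_j^2)$, always $\ge 1$. High values mark
  nodes whose input moves the whole system strongly.
* **Modal controllability** of ROI $i$ is
  $\phi_i = \sum_j (1-\lambda_j^2)\, v_{ij}^2 \in (1-\rho(A)^2,\, 1]$,
  weighting the node's participation in fast-decaying (hard-to-reach)
  modes. The two metrics tend to rank nodes in opposition, which the test
  suite asserts as a property.

Network-level values are unweighted means of the ROI values within each of
13 canonical functional networks; an `"unassigned"` pool is reported but
never modeled.

Because the estimated connectome is a correlation-scaled matrix, it is not
automatically stable. `stabilizeConnectome()` normalizes by
$A = W / (1 + \sigma_{\max}(W))$, the convention common in the
controllability-of-connectomes literature; the normalization is recorded in
the returned object so any alternative can be audited. The connectome
diagonal is zero going in (the partial correlation of a signal with itself
is undefined), and the symmetric eigensolver is mandated so the modal
formula's orthonormality assumption holds exactly.

## From raw timeseries to a connectome

`preprocessRun()` applies a fixed, contract-level ordering:

1. framewise displacement (FD) from the six rigid-body parameters — the sum
   of absolute backward differences, rotations converted to arc length at a
   50 mm radius;
2. band-stop ("notch") filtering of the motion parameters at 0.31–0.41 Hz
   before recomputing FD, because respiration inflates scanner motion
   estimates. At TR = 2 s the Nyquist frequency is 0.25 Hz, so the band is
   mapped through aliasing to its representable image (0.09–0.19 Hz): the
   respiratory oscillation itself aliases into the sampled parameters, and
   the filter must chase it where it lands. The mapped band is attached to
   the output;
3. censoring at notch-FD > 0.2 mm, then removal of any retained segment
   shorter than 5 frames;
4. run-level QC: exclusion at mean notch-FD > 0.5 mm or fewer than 50
   retained frames; task-level QC requires 150 retained frames summed over
   a task's included runs;
5. least-squares spectral interpolation of censored frames (below);
6. zero-phase second-order Butterworth band-pass at 0.009–0.08 Hz, applied
   identically to the data and to every column of the 36-parameter
   confound matrix (6 motion + global + white matter + CSF, each with its
   backward-difference derivative, square, and squared derivative);
7. ordinary least squares nuisance regression fit on retained frames only,
   with residuals evaluated at all frames and collinear columns dropped by
   label;
8. per-run linear detrend, z-scoring on retained frames, and concatenation
   of runs within a task. Censored frames are carried as a mask and never
   enter covariance estimation: interpolated values exist only so the
   temporal filters see no gaps.

The bands printed in some methods sections as "mHz" are interpreted as Hz
throughout (the standard BOLD pass band and respiratory notch band); both
are configurable in `pipelineConfig()`.

**Spectral interpolation.** Censored frames are reconstructed by a
least-squares fit of sine/cosine pairs at frequencies $k/\mathrm{span}$,
solved jointly across frequencies by rank-revealing QR and shared across
ROIs. The basis is capped at half the mean Nyquist frequency of the
retained (irregular) sampling: a basis approaching completeness makes the
extrapolation to censored frames ill-conditioned, while the 0.009–0.08 Hz
band-pass that follows discards everything above the BOLD band anyway. On a
pure 0.03 Hz sinusoid with 20% random censoring the reconstruction error at
censored frames is below 10% of the amplitude (asserted in the tests).

**Connectome estimation.** `estimatePrecision()` maximizes the
L1-penalized Gaussian log-likelihood (graphical LASSO, off-diagonal penalty
only, $\lambda = 0.1$ by default) on the sample correlation matrix of
retained frames, which makes the penalty scale-free. The solver is a block
coordinate-descent implementation (compiled inner lasso); because solver
choice is free but correctness is not, every fit is verified against the
Karush-Kuhn-Tucker conditions ($\Theta^{-1} - S = \lambda\,\Gamma$ with
$\Gamma_{ij} = \mathrm{sign}(\theta_{ij})$ on the support and
$|\Gamma_{ij}| \le 1$ off it) and the fit errors out above a $10^{-4}$
residual. At $\lambda = 0$ the same code path reproduces the inverse sample
correlation to $10^{-6}$, which the acceptance tests check as a two-route
comparison. Partial correlations are
$w_{ij} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$, both signs retained.
Frames from concatenated runs are treated as exchangeable samples (no
run-boundary autocorrelation correction), matching the procedure the
package reimplements.

## Group and drug contrasts

`fitModelSet()` fits one linear mixed model per (model set, metric, scan
context, network) cell with lme4: fixed effects are the condition coding
plus age, biological sex, and mean raw FD (computed per session and
context over all frames, before any filtering or censoring); a random
intercept per participant absorbs subject-specific levels, including the
aggregation over two sessions in the comparison group. Enumerating 2 model
sets x 2 metrics x 3 contexts x 13 networks yields 156 cells; no
multiple-comparisons correction is applied, deliberately.

Two genuinely open design points were resolved as follows:

* *One three-level model or two separate models?* The group-comparison set
  uses a single 3-level condition factor (TD reference, ADHD-placebo,
  ADHD-MPH): it shares the residual variance across contrasts and makes
  the two group contrasts jointly interpretable. The within-ADHD set is a
  separate binary-indicator model since the crossover design is not fully
  crossed.
* *Degrees of freedom.* p-values come from t statistics on the
  fixed-effect coefficients with residual-based degrees of freedom
  ($n_{\mathrm{obs}} - p$). This is the simplest defensible choice, it is
  recorded in every `ModelResult` row, and the type-I-error simulation in
  the acceptance suite confirms it is calibrated at the sample sizes the
  package targets. Satterthwaite-type corrections were left out to keep
  lme4 the only inferential dependency.

Mixed fits that fail outright are refit with a simplified variance
structure (fixed effects only) and flagged `variant = "fixed_only"`;
singular-but-successful fits keep their estimates and are flagged. Failed
cells are recorded with their error message so enumeration and results
always reconcile.

**Responder filtering.** A drug-condition participant enters the models
for a scan context only if their mean raw FD on drug is strictly lower
than on placebo in that context (an acute behavioral response); equal FD
is a non-response because a "reduction" must be strict. Comparison-group
participants are always included.

**Descriptive statistics.** `summaryTtest()` computes two-sample t-tests
from group summary statistics. The pooled-variance (Student) form is the
default because it reproduces both printed cohort-table p-values (0.32 for
age, 0.43 for IQ) at two decimals, whereas the Welch form gives 0.42 for
the IQ row; Welch remains available by argument. `chisqIndependence()` is
the uncorrected Pearson chi-squared test: the Yates-corrected variant is
far from the printed sex-row value, while the uncorrected p (0.615) sits
at the printed value's rounding boundary.

## The synthetic cohort generator

No participant data are distributable, so `makeCohort()` +
`simulateSession()` generate cohorts carrying exactly the statistical
structure the analysis assumes:

* **Dynamics.** Per subject, a block-structured symmetric coupling matrix
  (within-network weights 0.2, between-network 0.02, symmetric Gaussian
  jitter sd 0.02) rescaled to spectral radius 0.6, realized as a VAR(1)
  with independent unit-variance Gaussian innovations — the
  linear-Gaussian setting partial-correlation estimation assumes.
* **Group and drug effects.** The drug-free clinical condition adds
  `groupEffectSize` (default 0.2) to every within-network coupling of the
  designated effect networks before the rescale; the drug session scales
  that increment by `1 - drugRecoveryFraction` (default: full recovery).
  Keeping the spectral radius fixed across conditions raises the effect
  network's coupling *relative* to the rest of the connectome while
  leaving the dynamics equally stationary in every condition, so
  estimation quality is matched across groups and the injected effect —
  not an estimation artifact — drives the recovered contrasts. The mean
  within-effect-network weight remains strictly ordered
  placebo > drug > comparison, which the tests assert. The default effect
  size was chosen once so that the constructed phenotype matches the kind
  of effect the crossover design is powered to see at ~20 subjects per
  group (clearly significant group contrasts that vanish on drug); the
  direction and magnitude of real coupling differences are unknown, so
  this is a modeling choice of the generator, not a claim about biology.
* **Nuisance structure.** Slow per-ROI linear drift plus a slow cosine;
  AR(1)-smoothed global, white-matter and CSF signals with subject-specific
  loadings; and a rank-one motion artifact: spike magnitudes load onto all
  ROIs through subject-specific weights, reproducing the motion-FC
  confound the censoring and regression stages must remove (a seeded test
  checks that cleaning reduces the FD-signal coupling).
* **Motion.** Six-parameter random-walk jitter with a per-subject
  propensity (lognormal, sd 0.3 around the cell-level mm scale: drug-free
  clinical 0.016, on-drug 0.012, comparison 0.014) and Poisson-like
  displacement spikes (default 0.005/volume) whose magnitudes are drawn on
  an absolute mm scale so the censoring load is comparable across cells.
  Each clinical subject's on-drug jitter is their own placebo jitter times
  a lognormal reduction factor, so most — not all — subjects qualify as
  acute responders, and the FD covariate is identifiable within cells
  rather than collinear with condition. Baseline jitter sits below the
  0.2 mm censoring threshold; censoring is spike-driven. This emulates a
  well-behaved pediatric cohort after exclusions; it deliberately does not
  reproduce sustained high-motion epochs, respiratory quasi-periodicity,
  hemodynamic convolution, task-event structure, or scanner physics. What
  passing tests show is therefore that the *pipeline* recovers effects of
  the assumed generative form at realistic noise levels — not that it
  would do so under every artifact regime of real data.

Desk scale is 40 ROIs / 4 networks / 10 subjects per group; the full
284-ROI / 13-network layout is reachable through configuration, and the
full acquisition grid (two 150-volume rest runs, two 195-volume go/no-go
runs, four 185-volume rewarded go/no-go runs, TR 2 s) is the context
default. All stages are deterministic functions of the master seed, with
per-run sub-seeds derived by hashing, so identical configurations are
byte-identical end to end.

## Numerical choices and degenerate inputs

* Filters are second-order zero-phase (forward-backward) Butterworth
  designs; signals are demeaned before filtering and (for the band-stop)
  the mean is restored, which removes edge transients on offset inputs and
  makes the DC behavior exact.
* Derivatives are backward differences with first element 0; FD at the
  first frame is 0 by definition.
* An empty retained set is a legal censoring output; downstream stages
  refuse to fit on fewer than 2 retained frames with a QC error.
* z-scoring uses retained frames only; near-constant residuals (e.g. a
  pure trend after detrending) are left at zero rather than amplified by a
  tiny standard deviation.
* In the p > n regime the penalized estimator proceeds (regularization
  handles it) but logs a message.
* Rank-deficient confound matrices drop pivoted-out columns by label with
  a warning; an all-zero confound matrix leaves the data untouched.

## Problem sizes in the test suite

The suite runs at desk scale by choice: module tests use 8-40 ROI
fixtures; the end-to-end recovery check uses 20 replicate cohorts of 40
ROIs / 4 networks / 20 subjects per group with the rewarded go/no-go
context (four 185-volume runs — the grid's most data-rich context, where
connectome estimation noise is lowest relative to the injected effect);
the type-I-error check uses 200 replicate null metric tables at the
model-fitting stage, which is where the inferential calibration lives.
The full-scale 284-ROI layout exercises only configuration paths, not the
statistical claims.

## Known limitations

* The discrete-time linear model with a symmetric, stabilized correlation
  matrix as $A$ is a modeling convention; alternative stabilizations
  change absolute controllability values (though typically not
  rankings), which is why the normalization is recorded rather than
  hidden.
* Residual-based degrees of freedom are mildly anti-conservative for
  between-subject contrasts in small samples; the acceptance simulation
  bounds the effect at the targeted sizes.
* The generator's effect parameterization (coupling increments in named
  networks) is one of many mechanisms that could produce the observed
  controllability differences; recovery results should be read as internal
  consistency of the pipeline, not as evidence about mechanism.
* Spectral interpolation assumes the retained sampling still covers the
  BOLD band; under extreme censoring (>50%) reconstruction quality
  degrades and run-level QC is the intended guard.
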