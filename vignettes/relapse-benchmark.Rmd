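---
title: "Benchmarking relapse prediction on simulated leukemia remission curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking relapse prediction on simulated leukemia remission curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Molecular monitoring of leukemia (NPM1-mut/ABL transcripts in AML,
BCR-ABL1/ABL1 in CML) produces per-patient time series of the leukemic
burden during and after therapy. `relapsim` asks how well three
qualitatively different method families predict relapse from such series —
and how that ability depends on data *quality* (measurement error) and
*quantity* (sampling density):

* **MM** — refitting a mechanistic ODE model of the disease to the observed
  window and simulating it forward;
* **GLM** — logistic regression on explicit, hand-crafted response features;
* **NN** — a bidirectional LSTM trained end-to-end on the raw series.

Because real cohorts with dense sampling do not exist, the package builds a
fully synthetic study: cohorts are simulated from the mechanistic models,
degraded to clinical data quality in controlled steps, and every method is
scored against the simulation ground truth under stratified 10-fold
cross-validation.

## Disease models

### AML (time unit: days)

Four compartments: healthy (H) and leukemic (L) stem cells, each either
quiescent (Q, shared carrying capacity $K_Q$) or active (A, shared capacity
$K_A$). With occupancy factors $o_Q = 1-(Q_H+Q_L)/K_Q$ and
$o_A = 1-(A_H+A_L)/K_A$, for $i \in \{H, L\}$:

$$
\begin{aligned}
\dot Q_i &= t_{AQ,i}\,A_i\,o_Q - t_{QA,i}\,Q_i\,o_A\\
\dot A_i &= t_{QA,i}\,Q_i\,o_A - t_{AQ,i}\,A_i\,o_Q
           + p_i A_i o_A - d_i A_i - c\,u(t)\,A_i
\end{aligned}
$$

with $u(t) = 1$ during a chemotherapy cycle and 0 otherwise. The shared
occupancy factors encode niche competition: the healthy and leukemic clones
fight for the same space, so healthy recovery after chemotherapy caps
leukemic regrowth. The observable is the leukemic fraction of the stem-cell
pool in percent, $100\,(Q_L+A_L)/\sum$, matching the scale of clinical
NPM1-mut/ABL ratios.

Two of the eleven parameters are patient-specific: the leukemic
proliferation rate $p_L$ (regrowth speed, hence relapse timing) and the
leukemic quiescence exit $t_{QA,L}$ (how quickly the chemo-protected
reservoir drains into the drug-exposed active pool, hence nadir depth and
late reseeding). The other nine encode the shared treatment dynamics and
are population constants — which is also what makes per-patient refitting
well-posed.

The diagnosis state is fixed (active niche 90% leukemic, healthy cells
mostly sheltered in quiescence). Initial-state heterogeneity is therefore
*not* emulated; the diagnosis burden varies only through the early kill
dynamics. This is a known simplification — see Limitations.

### CML (time unit: months)

Three compartments: quiescent ($X$) and active ($Y$) leukemic stem cells
and immune effector cells ($Z$):

$$
\begin{aligned}
\dot X &= p_{YX} Y - p_{XY} X\\
\dot Y &= p_{XY} X - p_{YX} Y + p_Y Y (1 - Y/K_Y)
          - e_{TKI}\,\mathrm{dose}(t)\,Y - m\,Y Z\\
\dot Z &= r_Z - a Z + p_Z\,Z\,\frac{Y}{K_Z + Y^2}
\end{aligned}
$$

with $\mathrm{dose}(t) \in \{1, \tfrac12, 0\}$. The recruitment term is the
*immune window*: it peaks at the intermediate load $Y = \sqrt{K_Z}$ and is
suppressed both when the leukemia is nearly gone and when it is
overwhelming. After TKI cessation the outcome is a race between leukemic
regrowth ($p_Y$) and immune expansion through the window — which is why
roughly half the patients maintain treatment-free remission, and why the
system's response to a dose reduction carries prognostic information. The
observable is $100\,Y/K_Y$ (the model analog of BCR-ABL1/ABL1).

Seven of the thirteen quantities are patient-specific
($p_{XY}, p_{YX}, e_{TKI}, m, p_Z, K_Z, Z_0$); growth, capacity, immune
production/decay and the initial tumour load are shared.

## Labels

* AML **relapse**: after first dropping below 1%, the dense noise-free
  burden exceeds 1% again at any grid point within 24 months of treatment
  start. Patients that never reach 1% ("no remission") are excluded and
  resampled, mirroring the study-population definition.
* CML **molecular recurrence**: burden above 0.1% (loss of MR3) for a
  contiguous span of at least one month within ten years after cessation.
  The one-month persistence rule discards isolated noise-free blips;
  on the monthly grid it amounts to two consecutive exceedances.

Labels are always computed on the dense noise-free course (variant D) and
are untouched by every degradation transform.

## The synthetic cohorts

The empirical parameter distributions of the original fits are not
deposited, so the package ships its own reference tables
(`aml_base_table()`, 25 rows; `cml_base_table()`, 30 rows) and samples
around them:

* **AML**: rows are drawn with replacement and the patient-specific
  parameters multiplied by a log-normal jitter (`SD` 0.10); relative jitter
  keeps rates positive and prevents duplicate patients. The table spans
  $p_L \in [0.08, 0.18]$/day and $t_{QA,L} \in [0.05, 0.28]$/day minus the
  refractory corner (fast regrowth with a slow reservoir, which the
  remission filter would reject wholesale).
* **CML**: the seven free parameters are drawn from a Gaussian copula whose
  marginals are the interpolated empirical quantiles of the table and whose
  rank correlations match the table's Spearman matrix, preserving the
  mutual correlations of the fitted population. The table itself is built
  deterministically from two latent axes — TKI response strength and immune
  competence, positively coupled — plus independent reservoir kinetics.
* **Cessation times**: truncated normal, calibrated by closed-form
  truncated-normal moments so the *realized* mean and SD are 92 and 28.2
  months, truncated at 24 months (patients stop only after sustained
  remission). A kernel-density sampler is not reproducible without the 21
  source values; the truncated normal pins the two printed moments. Its
  median sits slightly below its mean (the truncation skews right), so the
  median dense CML window holds 92–93 monthly points.
* **Chemotherapy schedules**: 3–5 one-week cycles, first at day 0,
  starts spaced 33–38 days — an induction/consolidation pattern whose
  multiplicities are a calibrated guess (the observed schedule list is not
  published). Under the refined scheme this yields the intended median of
  7 measurements.

Calibration anchors (checked by the acceptance suite): 39 weekly AML
measurements in the 9-month input window, median 93 monthly CML
measurements to cessation, AML relapse fraction ≈ 0.4–0.5 and ≥ 80% of
patients with ≥ 3 log~10~ of burden decline from diagnosis, CML recurrence
≈ 0.5.

The weekly AML grid starts one week after treatment start: the diagnostic
work-up at day 0 is not part of the molecular monitoring series, and a
grid including day 0 would hold 40 in-window points instead of the
calibrated 39.

## The data-quality ladder

| variant | transform | defaults |
|---|---|---|
| D | dense, exact | AML weekly, CML monthly |
| DN | + log-normal noise per point | SD 0.3 dex (AML), 0.35 dex (CML) |
| SN | + per-patient subsampling | AML counts 3–6 (median 4), CML 15–35 (median 25) |
| AP | + detection limit | 0.01%, censored values stored at the limit |
| AS | refined scheme | see below |

Sparsification always keeps the first and last point of the input window
and draws the rest uniformly; the post-window tail is thinned at the same
rate so the label horizon stays realistic. The AML count distribution is
skewed low (probabilities 0.25/0.35/0.25/0.15 on 3/4/5/6) to reproduce the
clinical median of 4 robustly.

**AS (AML)**: one measurement at the end of each chemotherapy cycle plus
one every six weeks after treatment end until month 9 — same assay budget,
informative placement (cycle-end lows expose the reservoir, the six-weekly
tail exposes regrowth). The clinical-note wording "first day of each cycle"
is available as `aml_as_at_cycle_start = TRUE`. **AS (CML)**: the course is
re-simulated with half dose over the final 12 months before cessation
(monthly sampling during that year; sampling before it matches AP exactly,
so any information gain is attributable to the perturbation).

## Features for the GLM

* **AML (5)**: fitted log10 burden at diagnosis $y_0$; shared in-cycle and
  between-cycle slopes $a, b$ from a continuous segmented regression with
  breakpoints at the cycle boundaries (the model is linear in
  $(y_0, a, b)$ via cumulative in-/out-of-cycle time, so three points
  suffice — sharing one slope across cycles is an identifiability choice at
  clinical sparsity); the overall elimination slope $\alpha$ (separate OLS
  up to treatment end); and the lowest measured post-treatment burden $n$.
* **CML (7)**: the bi-exponential remission course summarized by its
  two-straight-line approximation on the log scale — intercepts/slopes
  $A, \alpha, B, \beta$ (continuity enforced, breakpoint by exhaustive
  search over interior measurement times, earliest time on ties; $B$
  reported as the second segment's intercept at $t=0$), the fit RMSE
  $\sigma$, the cessation time, and the last measured value before
  cessation (before the half-dose year for AS).
* **CML AS (+4)**: slope $\gamma$ and intercept $C$ of a line over the
  half-dose window, its RMSE, and the last value before cessation. The
  source description of "C" is ambiguous between an intercept and a
  deviation; the package ships both ($C$ and $\sigma_{half}$), giving 11 AS
  features.

Censored values enter all fits at the detection limit — exactly as stored.

## Predictors

* **MM**: minimizes the sum of squared log10 residuals over the free
  parameters. Censored points contribute one-sidedly
  ($\max(0, \log_{10}\hat y - \log_{10}\mathrm{LOD})^2$): an undetectable
  measurement only penalizes simulations that predict detectable disease.
  AML (2 parameters): bounded L-BFGS-B on the log scale, 5 restarts from
  prior-sampled starts — any bounded quasi-Newton method fills the
  sequential-quadratic-programming role here. CML (7 parameters): a
  generational GA (population 50, 40 generations, tournament size 3,
  Gaussian mutation, elitism 2) with a local polish, to escape the local
  minima of the immune-window landscape. Box bounds are the prior span
  widened by a factor 2. The prediction is hard 0/1: the forward-simulated
  course either crosses the relapse threshold or not; a fitted AML course
  that never reaches remission is predicted as relapse.
* **GLM**: ridge-stabilized IRLS ($\lambda = 10^{-4}$, intercept
  unpenalized) on z-scored features; the ridge keeps coefficients finite
  under the complete separation that noise-free variants produce.
  Verified against an independent optimizer in the tests.
* **NN**: bidirectional LSTM (32 units per direction by default), dense
  ReLU head (16), sigmoid output, binary cross-entropy, Adam
  ($10^{-3}$), minibatch 32, early stopping on validation accuracy
  (patience 10), 10 independently initialized restarts keeping the highest
  validation accuracy (ties: lowest run index; single-class validation
  falls back to validation loss). Channels per measurement: time scaled by
  the patient's window length, log10 burden min–max scaled to $[-1,1]$
  with training-fold statistics, and the censoring flag. Sequences are
  front-aligned; the readout is the hidden state at each sequence's last
  real step, so padded steps receive exactly zero gradient. No deep
  learning framework is available to R in this environment, so the network
  (batched forward pass, backpropagation through time, Adam) is
  implemented in RcppArmadillo and validated against finite-difference
  gradients. Its layer sizes are stand-ins — the original architecture
  details are not published.

## Evaluation protocol

Stratified 10-fold cross-validation; all methods are scored on identical
test folds. The MM needs no training but is fit per patient on the same
degraded input of the evaluated variant. The NN carves a stratified 10%
inner validation split out of its training folds for restart selection and
early stopping. Reported uncertainty is the SD of accuracy across folds.
All stage seeds derive deterministically from one master seed
(`derive_seed`), so a run is reproducible end to end; network training is
additionally deterministic because initialisation and shuffling draw from
R's RNG.

## Numerical choices

* Integration: compiled adaptive Cash-Karp RK4(5), relative tolerance
  $10^{-8}$ for reported courses ($10^{-5}$ inside fitting objectives);
  dose discontinuities are handled exactly by restarting the step at each
  breakpoint while carrying the step size across smooth boundaries. Both
  systems are non-stiff at the shipped parameter ranges;
  `deSolve::lsoda` on the R-level right-hand sides is the independent
  cross-check in the test suite.
* Burden floor $10^{-6}$% before any log10, applied uniformly.
* Two-segment breakpoint ties resolve to the earliest candidate time;
  degenerate segmented designs (all points in one treatment regime)
  collapse both slopes to the single-line slope.
* Truncated-normal calibration by Nelder-Mead on the closed-form moment
  equations (deterministic, no simulation in the loop).

## Desk-scale problem sizes

The shipped analyses and acceptance checks run at 200–1000 patients
(sampling calibration: 1000; method experiments: 500 with 10-fold CV;
parameter recovery: 50), with the network reduced to 16 units / 30 epochs /
3 restarts on the 39-point dense variants and at its default size on the
short AP/AS series. These sizes give fold-level accuracy SDs of 3–7
percentage points, which is the resolution at which the qualitative
claims (monotone decline along the ladder, refined-scheme improvement)
are asserted.

## What passing tests do and do not show

The generator emulates remission kinetics, clinical sampling frequencies,
log-scale assay noise, a detection limit, and treatment schedules. It does
**not** emulate: initial-state heterogeneity (AML diagnosis state is
fixed), per-sample varying detection limits, measurement-time jitter
around nominal visits, dropout/irregular follow-up, competing clinical
events, or any disease biology outside the two ODE structures — in
particular, model misspecification for the MM is absent by construction on
variant D, which is precisely why its dense-data accuracy is near 100% and
should be read as a self-consistency ceiling, not a clinical claim.
Accuracies measured here characterize the *relative* behaviour of the
three method families under controlled degradation, not expected
performance on real patients.

## Known limitations

* The exact published equation set behind the two models is not in the
  available text; the structures implemented here follow the documented
  compartment diagrams, and the right-hand sides are isolated behind
  `aml_rhs`/`cml_rhs` so an alternative form can be swapped in.
* The AS measurement rule ends at the last six-week grid point before
  month 9, typically a month short of the window end that AP's anchored
  subsampling always retains; for pattern-based predictors this trades
  away late-regrowth signal against better mid-course coverage, and the
  network needs its full training budget for the balance to come out in
  favour of AS.
* CML mechanistic refitting at clinical sparsity is expensive (a GA per
  patient) and its 7-parameter identifiability is intrinsically poor —
  matching the motivating observation that mechanistic prediction degrades
  fastest with CML data quality.
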