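# relapsim

Simulation-based benchmark of relapse prediction from leukemia remission
time courses.

## The problem

Treatment decisions for myeloid leukemias are usually based on static
markers measured at diagnosis, while the *dynamics* of molecular disease
monitoring — NPM1-mut/ABL transcript ratios in AML, BCR-ABL1/ABL1 in CML —
are rarely exploited. Whether a patient will relapse after chemotherapy
(AML) or lose treatment-free remission after TKI cessation (CML) is,
however, partly encoded in those time series. How much of it a method can
recover depends on the method *and* on the data: how many measurements,
how noisy, and whether low values are censored at the assay's detection
limit.

`relapsim` builds a fully controlled in-silico version of this question.
It simulates labeled patient cohorts from mechanistic ODE models of the
two diseases, degrades the simulated remission curves step by step to
clinical data quality, and benchmarks three prediction strategies under
stratified 10-fold cross-validation:

* **MM** — mechanistic refitting: the patient-specific model parameters
  are re-estimated from the observed window by minimizing
  $\sum_i (\log_{10}\hat y(t_i) - \log_{10}y_i)^2$ (censored points
  one-sided), and the fitted model is simulated forward across the
  prediction horizon;
* **GLM** — logistic regression on explicit response features (elimination
  slope $\alpha$, segmented-regression slopes $a, b$, diagnosis burden
  $y_0$, post-treatment nadir $n$ for AML; the bi-linear remission
  parameters $A, \alpha, B, \beta$, fit deviation $\sigma$, cessation time
  and last value for CML);
* **NN** — a bidirectional LSTM classifier trained end-to-end on the raw
  (time, log-burden, censored) sequences.

The data-quality ladder: **D** (dense, exact: weekly for AML, monthly for
CML) → **DN** (log-normal measurement noise) → **SN** (clinical sampling
density: median 4 points for AML, 25 for CML) → **AP** (detection limit
0.01%, "artificial patients") → **AS** (refined schemes: AML measurements
at chemotherapy-cycle ends plus six-weekly follow-ups; CML a half-dose
year before cessation with monthly sampling).

AML relapse is defined as the leukemic burden re-exceeding 1% within 24
months of treatment start; CML recurrence as burden above 0.1% (loss of
MR3) for at least one month within ten years after cessation. Labels are
always computed on the noise-free ground truth.

## Worked example

```r
library(relapsim)

co <- generate_cohort(cohort_config("AML", n_patients = 100, seed = 7))
print(co)
#> <cohort> AML, 100 patients (1 excluded by remission filter), relapse fraction 0.41

cfg <- eval_config(k = 5, seed = 42, degrade = degrade_config(seed = 42),
                   nn = nn_config(hidden = 16, epochs = 30, patience = 6,
                                  restarts = 3),
                   mm = list(restarts = 3))
rep <- run_experiment(co, variants = c("D", "AP"),
                      methods = c("MM", "GLM", "NN"), cfg = cfg)
print(rep)
#> <eval_report> 100 patients, 5 folds
#>  disease variant method mean    sd
#>      AML      AP    GLM 0.73 0.084
#>      AML       D    GLM 0.90 0.071
#>      AML      AP     MM 0.77 0.160
#>      AML       D     MM 1.00 0.000
#>      AML      AP     NN 0.75 0.106
#>      AML       D     NN 0.76 0.065
```

Reading the table: on dense noise-free data (D) the mechanistic model is
exact — it is the generative model, so refitting its two free parameters
recovers the ground truth and the cross-validated accuracy is 1.0. At
clinical data quality (AP: median 4 noisy measurements with a detection
limit) all three methods drop into the 0.7–0.8 band, and the mean ± SD
across folds shows they are no longer clearly separated: data quality, not
method choice, limits what is achievable. The network needs more patients
than this small example to be competitive on dense series.

The `analysis/` scripts run the full study at desk scale and write their
tables under `results/`:

```sh
Rscript analysis/01_generate_cohorts.R      # cohorts + calibration summary
Rscript analysis/02_degradation_ladder.R    # the D/DN/SN/AP/AS ladder
Rscript analysis/03_benchmark_predictors.R  # AML ladder x method grid
Rscript analysis/04_improved_schemes.R      # AS vs AP, both diseases
```

`vignettes/relapse-benchmark.Rmd` documents the models, the synthetic
cohort calibration, every tunable default, and the design decisions.

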