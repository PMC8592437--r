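# Shared fixtures: built once per test run, in code.

# four-cycle schedule used by constructed examples (days)
fixture_schedule_aml <- function() {
  aml_schedule(cbind(c(0, 35, 70, 105), c(6, 41, 76, 111)))
}

fixture_schedule_cml <- function(t_stop = 90) cml_schedule(t_stop)

# small cached cohorts (generation is fast but used by several files)
.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(disease = "AML", n = 40, seed = 301) {
  key <- paste(disease, n, seed, sep = "_")
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_cohort(
      cohort_config(disease, n_patients = n, seed = seed))
  .fixture_env[[key]]
}

# exact straight-line AML input at given times (months), log10 slope s
fixture_line_traj <- function(times, intercept, slope, id = "line") {
  new_trajectory(id, "AML", "SN", times, 10^(intercept + slope * times))
}
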