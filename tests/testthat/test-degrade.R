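# Data-quality ladder transforms and their invariants.

test_that("multiplicative noise has the configured log10 spread", {
  co <- fixture_cohort("AML", 4)
  d <- co$records[[1]]$dense
  expect_identical(add_noise(d, 0, seed = 1)$burden_pct, d$burden_pct)
  expect_error(add_noise(add_noise(d, 0.1, seed = 1), 0.1), "dense")

  big <- new_trajectory("mc", "AML", "D", seq_len(1e5), rep(1, 1e5))
  dn <- add_noise(big, 0.3, seed = 2)
  expect_true(all(dn$burden_pct > 0))
  expect_equal(sd(log10(dn$burden_pct / big$burden_pct)), 0.3,
               tolerance = 0.01)
  expect_identical(dn$time_months, big$time_months)
  expect_identical(dn$variant[1], "DN")
})

test_that("sparsification keeps window anchors and stays a subset", {
  co <- fixture_cohort("AML", 20)
  cd <- list(values = 3:6, probs = c(0.25, 0.35, 0.25, 0.15))
  for (r in co$records) {
    dn <- add_noise(r$dense, 0.3, seed = derive_seed(1, r$id))
    sn <- sparsify(dn, "AML", r$schedule, cd, seed = derive_seed(2, r$id))
    expect_true(all(sn$time_months %in% dn$time_months))
    expect_false(is.unsorted(sn$time_months, strictly = TRUE))
    win_dn <- dn$time_months[dn$time_months <= 9]
    win_sn <- sn$time_months[sn$time_months <= 9]
    expect_equal(win_sn[1], win_dn[1])                      # first kept
    expect_equal(max(win_sn), max(win_dn))                  # last kept
    expect_true(length(win_sn) %in% 3:6)
  }
  # requesting more points than available keeps everything, with a warning
  short <- new_trajectory("s", "AML", "DN", c(1, 4, 8), c(5, 1, 0.5))
  expect_warning(
    out <- sparsify(short, "AML", fixture_schedule_aml(),
                    list(values = 10, probs = 1), seed = 1),
    "keeping all")
  expect_equal(out$time_months, short$time_months)
})

test_that("detection limit censors exactly the sub-threshold points", {
  tr <- new_trajectory("c", "AML", "SN", 1:6,
                       c(5, 0.005, 0.2, 0.001, 0.009, 3))
  ap <- apply_detection_limit(tr, 0.01)
  expect_identical(sum(ap$censored), 3L)          # brute-force count
  expect_true(all(ap$burden_pct[ap$censored] == 0.01))
  expect_identical(ap$burden_pct[!ap$censored], tr$burden_pct[!ap$censored])
  expect_identical(ap$variant[1], "AP")

  none <- apply_detection_limit(tr, 1e-4)
  expect_identical(none$burden_pct, tr$burden_pct)
  expect_identical(sum(none$censored), 0L)
  # lowering the limit never censors more
  for (lod in c(0.5, 0.05, 0.005, 5e-4))
    expect_lte(sum(apply_detection_limit(tr, lod / 2)$censored),
               sum(apply_detection_limit(tr, lod)$censored))
})

test_that("the AML refined scheme measures cycle ends plus six-week follow-ups", {
  co <- fixture_cohort("AML", 20)
  cfg <- degrade_config(seed = 4)
  counts <- vapply(co$records, function(r) {
    tr <- as_scheme(r, cfg, seed = derive_seed(9, r$id))
    ends <- relapsim:::days_to_months(r$schedule$cycles[, 2])
    expect_true(all(ends %in% tr$time_months))
    expect_lte(max(tr$time_months), 9)
    nrow(tr)
  }, 0L)
  expect_true(all(counts >= 4 & counts <= 8))
  # first-day-of-cycle option measures cycle starts instead
  cfg2 <- degrade_config(seed = 4, aml_as_at_cycle_start = TRUE)
  r <- co$records[[1]]
  tr2 <- as_scheme(r, cfg2, seed = 1)
  starts <- relapsim:::days_to_months(r$schedule$cycles[-1, 1])
  expect_true(all(starts %in% tr2$time_months))
})

test_that("the CML half-dose scheme only perturbs the final year", {
  cc <- fixture_cohort("CML", 8)
  cfg <- degrade_config(seed = 4)
  r <- cc$records[[1]]
  ts <- r$schedule$t_stop
  ap <- relapsim:::degrade_patient(r, "AP", cfg)
  as_ <- relapsim:::degrade_patient(r, "AS", cfg)
  # sampling before the half-dose year matches AP exactly
  pre_ap <- ap$time_months[ap$time_months < ts - 12 - 1e-9]
  pre_as <- as_$time_months[as_$time_months < ts - 12 - 1e-9]
  expect_equal(pre_as, pre_ap)
  # monthly sampling during the half-dose year
  expect_equal(sum(as_$time_months >= ts - 12 - 1e-9), 13)

  # with e_TKI = 0 the dose change is inert: dense courses coincide
  p0 <- r$params
  p0$e_TKI <- 0
  tt <- seq(0, ts, by = 5)
  full <- simulate_course(p0, cml_schedule(ts), tt)
  half <- simulate_course(p0, cml_schedule(ts, ts - 12), tt)
  expect_equal(full$burden_pct, half$burden_pct, tolerance = 1e-8)

  expect_error(as_scheme(list(disease = "CML", id = "x", params = r$params,
                              schedule = cml_schedule(10)),
                         cfg, ap_traj = ap), "half-dose window")
})

test_that("windows split at month 9 (AML) and cessation (CML)", {
  co <- fixture_cohort("AML", 4)
  r <- co$records[[1]]
  sw <- split_windows(r$dense, "AML", r$schedule)
  wk <- relapsim:::days_to_months(seq(7, relapsim:::months_to_days(9), by = 7))
  expect_equal(sw$input$time_months, wk)     # exactly the weekly points
  expect_equal(sw$horizon, c(9, 24))

  cc <- fixture_cohort("CML", 4)
  for (r in cc$records) {
    sw <- split_windows(r$dense, "CML", r$schedule)
    expect_lte(max(sw$input$time_months), r$schedule$t_stop + 1e-9)
    expect_equal(sw$horizon[1], r$schedule$t_stop)
  }
  empty <- new_trajectory("e", "AML", "D", c(12, 15), c(1, 2))
  expect_error(split_windows(empty, "AML", r$schedule), "empty input")
})

test_that("ladder invariants hold across a degraded cohort", {
  co <- fixture_cohort("AML", 25)
  cfg <- degrade_config(seed = 8)
  D <- degrade_cohort(co, "D", cfg)
  DN <- degrade_cohort(co, "DN", cfg)
  SN <- degrade_cohort(co, "SN", cfg)
  AP <- degrade_cohort(co, "AP", cfg)
  for (i in seq_along(D)) {
    expect_identical(DN[[i]]$time_months, D[[i]]$time_months)
    expect_true(all(SN[[i]]$time_months %in% D[[i]]$time_months))
    # AP differs from SN only where censored
    expect_identical(AP[[i]]$time_months, SN[[i]]$time_months)
    same <- AP[[i]]$burden_pct == SN[[i]]$burden_pct
    expect_true(all(same | AP[[i]]$censored))
    # same noise realization where the ladder overlaps
    idx <- match(SN[[i]]$time_months, DN[[i]]$time_months)
    expect_equal(SN[[i]]$burden_pct, DN[[i]]$burden_pct[idx])
  }
  # deterministic transforms under a fixed config seed
  SN2 <- degrade_cohort(co, "SN", cfg)
  expect_identical(SN, SN2)
  # labels come from the dense ground truth and survive degradation untouched
  expect_identical(cohort_labels(co),
                   vapply(co$records, function(r)
                     label_relapse(r$dense, "AML", r$schedule), TRUE))
})
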