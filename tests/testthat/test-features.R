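# Explicit time-course features: segmented regression (AML) and the
# two-straight-line remission approximation (CML).

test_that("a single straight line collapses the AML segmented fit", {
  sch <- fixture_schedule_aml()
  tt <- relapsim:::days_to_months(seq(7, 270, by = 14))
  tr <- fixture_line_traj(tt, intercept = 1.2, slope = -0.8)
  f <- aml_features(tr, sch)
  expect_equal(unname(f["a"]), -0.8, tolerance = 1e-9)
  expect_equal(unname(f["b"]), -0.8, tolerance = 1e-9)
  expect_equal(unname(f["alpha"]), -0.8, tolerance = 1e-9)
  expect_equal(unname(f["y0"]), 1.2, tolerance = 1e-9)
  expect_error(aml_features(tr[1:2, ], sch), "insufficient")
})

test_that("the sawtooth slopes are recovered exactly", {
  sch <- fixture_schedule_aml()
  tt <- relapsim:::days_to_months(seq(7, 270, by = 7))
  cyc <- relapsim:::days_to_months(sch$cycles)
  ga <- vapply(tt, function(ti) sum(pmax(0, pmin(ti, cyc[, 2]) - cyc[, 1])), 0)
  gb <- tt - ga
  y <- 1.5 + (-2) * ga + 1 * gb          # in-cycle slope -2, between +1
  tr <- new_trajectory("saw", "AML", "SN", tt, 10^y)
  f <- aml_features(tr, sch)
  expect_equal(unname(f["a"]), -2, tolerance = 1e-6)
  expect_equal(unname(f["b"]), 1, tolerance = 1e-6)
  expect_equal(unname(f["y0"]), 1.5, tolerance = 1e-6)
  # n equals the brute-force minimum over post-treatment measurements
  tend <- relapsim:::days_to_months(111)
  expect_equal(unname(f["n"]), min(y[tt > tend]))
})

test_that("CML bi-linear fit recovers constructed two-segment data", {
  sch <- fixture_schedule_cml(40)
  tt <- seq(0, 40, by = 2)
  bp <- 6
  y <- ifelse(tt <= bp, 2 - 1.5 * tt, (2 - 1.5 * bp) - 0.2 * (tt - bp))
  tr <- new_trajectory("seg", "CML", "SN", tt, 10^y)
  f <- cml_features(tr, sch)
  expect_equal(unname(f["A"]), 2, tolerance = 1e-9)
  expect_equal(unname(f["alpha"]), -1.5, tolerance = 1e-9)
  expect_equal(unname(f["beta"]), -0.2, tolerance = 1e-9)
  expect_equal(unname(f["sigma"]), 0, tolerance = 1e-9)
  # B is the second segment's intercept extrapolated to t = 0
  expect_equal(unname(f["B"]), 2 + bp * (-1.5 + 0.2), tolerance = 1e-9)
  expect_equal(unname(f["t_stop"]), 40)
  expect_equal(unname(f["last_value"]), y[length(y)])
  expect_length(f, 7)

  # degenerate single line: both segments share its slope, sigma = 0
  y1 <- 1 - 0.3 * tt
  f1 <- suppressWarnings(cml_features(
    new_trajectory("l", "CML", "SN", tt, 10^y1), sch))
  expect_equal(unname(f1["alpha"]), -0.3, tolerance = 1e-9)
  expect_equal(unname(f1["beta"]), -0.3, tolerance = 1e-9)
  expect_equal(unname(f1["sigma"]), 0, tolerance = 1e-9)

  expect_error(cml_features(tr[1:3, ], sch), "insufficient")
  cens <- tr
  cens$censored <- TRUE
  expect_error(cml_features(cens, sch), "censored")
})

test_that("breakpoint search equals the exhaustive enumeration oracle", {
  set.seed(42)
  for (rep in 1:20) {
    k <- sample(6:30, 1)
    tt <- sort(runif(k, 0, 60))
    y <- -0.5 * tt + 0.4 * pmax(0, tt - 25) + rnorm(k, 0, 0.3)
    got <- relapsim:::fit_two_segments(tt, y)
    # independent oracle: plain enumeration with direct least squares
    oracle <- Inf
    for (bp in tt[2:(k - 1)]) {
      X <- cbind(1, tt, pmax(0, tt - bp))
      cf <- tryCatch(qr.solve(X, y), error = function(e) NULL)
      if (is.null(cf)) next
      sse <- sum((y - X %*% cf)^2)
      if (sse < oracle) oracle <- sse
    }
    expect_equal(got$sigma^2 * k, oracle, tolerance = 1e-8)
    # nesting: the two-segment SSE never exceeds the single-line SSE
    expect_lte(got$sigma^2 * k, sum(lm(y ~ tt)$residuals^2) + 1e-10)
  }
})

test_that("feature matrices have fixed shapes and are deterministic", {
  co <- fixture_cohort("AML", 20)
  cfg <- degrade_config(seed = 8)
  ap <- degrade_cohort(co, "AP", cfg)
  fm <- feature_matrix(co, ap, "AP")
  expect_identical(setdiff(names(fm), c("patient_id", "label")),
                   c("alpha", "n", "y0", "a", "b"))     # exactly 5 features
  expect_identical(fm, feature_matrix(co, ap, "AP"))

  cc <- fixture_cohort("CML", 10)
  capc <- degrade_cohort(cc, "AP", cfg)
  fmc <- suppressWarnings(feature_matrix(cc, capc, "AP"))
  expect_length(setdiff(names(fmc), c("patient_id", "label")), 7)
  casc <- degrade_cohort(cc, "AS", cfg)
  fms <- suppressWarnings(feature_matrix(cc, casc, "AS"))
  expect_length(setdiff(names(fms), c("patient_id", "label")), 11)
  expect_true(all(c("gamma", "C", "sigma_half", "last_pre_stop")
                  %in% names(fms)))
})

test_that("features ignore measurements beyond the input window", {
  co <- fixture_cohort("AML", 5)
  r <- co$records[[1]]
  inp <- split_windows(r$dense, "AML", r$schedule)$input
  f1 <- aml_features(inp, r$schedule)
  f2 <- aml_features(split_windows(r$dense, "AML", r$schedule)$input,
                     r$schedule)
  expect_identical(f1, f2)
  # via the matrix path: post-window points do not change the features
  full <- list(r$dense)
  trimmed <- list(r$dense[r$dense$time_months <= 9, ])
  co1 <- co; co1$records <- co$records[1]
  expect_equal(feature_matrix(co1, full, "D"),
               feature_matrix(co1, trimmed, "D"))
})
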