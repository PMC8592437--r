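# Disease-model right-hand sides, forward simulation, observable, labeling.

test_that("rhs identity and absorbing-state cases", {
  sch <- fixture_schedule_aml()
  p0 <- aml_parameters(t_QA_H = 0, t_AQ_H = 0, p_H = 0, d_H = 0, t_QA_L = 0,
                       t_AQ_L = 0, p_L = 0, d_L = 0, c = 0)
  expect_equal(aml_rhs(c(10, 20, 30, 40), 5, p0, sch), rep(0, 4))

  # leukemic compartments absorb at zero
  p <- aml_parameters()
  d <- aml_rhs(c(1e4, 1e5, 0, 0), 50, p, sch)
  expect_equal(d[3], 0)
  expect_equal(d[4], 0)

  # CML leukemia-free case: dX = -p_XY X, dZ = r_Z - a Z
  pc <- cml_parameters()
  sc <- fixture_schedule_cml()
  d <- cml_rhs(c(500, 0, 80), 10, pc, sc)
  expect_equal(d[1], -pc$p_XY * 500)
  expect_equal(d[2], pc$p_XY * 500)
  expect_equal(d[3], pc$r_Z - pc$a * 80)

  expect_error(aml_rhs(c(NaN, 1, 1, 1), 0, p, sch), "blow-up")
})

test_that("single active species reduces to the logistic equation", {
  # with transitions, differentiation and chemo off, dA/dt = p A (1 - A/K_A)
  p <- aml_parameters(t_QA_H = 0, t_AQ_H = 0, p_H = 0.1, d_H = 0,
                      t_QA_L = 0, t_AQ_L = 0, p_L = 0, d_L = 0, c = 0)
  sch <- aml_schedule(cbind(0, 6))
  A <- 1e4
  d <- aml_rhs(c(0, A, 0, 0), 3, p, sch)
  expect_equal(d[2], 0.1 * A * (1 - A / p$K_A), tolerance = 1e-12)

  # full simulation against the closed-form logistic solution
  tt <- c(10, 30, 60, 100) # days
  st <- relapsim:::simulate_states(p, sch, relapsim:::days_to_months(tt),
                                   state0 = c(0, A, 0, 0))
  K <- p$K_A; r <- 0.1
  anal <- K * A * exp(r * tt) / (K + A * (exp(r * tt) - 1))
  expect_equal(st[, 2], anal, tolerance = 1e-6)
})

test_that("CML immune compartment has the closed-form leukemia-free limit", {
  pc <- cml_parameters(X0 = 0, Y0 = 0, Z0 = 0)
  sc <- fixture_schedule_cml(50)
  st <- relapsim:::simulate_states(pc, sc, c(20 / pc$a, 1000))
  expect_equal(st[1, 3], pc$r_Z / pc$a, tolerance = 1e-3)  # by t = 20/a
  expect_equal(st[2, 3], pc$r_Z / pc$a, tolerance = 1e-8)

  # immune-window recruitment peaks at Y = sqrt(K_Z)
  recruit <- function(Y) {
    d <- cml_rhs(c(0, Y, 100), 5, pc, sc)
    d[3] - (pc$r_Z - pc$a * 100)
  }
  ypk <- sqrt(pc$K_Z)
  expect_gt(recruit(ypk), recruit(0.1 * ypk))
  expect_gt(recruit(ypk), recruit(10 * ypk))
})

test_that("burden observable matches its definition and floors at zero", {
  pa <- aml_parameters()
  expect_equal(burden(c(10, 10, 0, 0), pa), 1e-6)   # floored zero
  expect_equal(burden(c(0, 0, 5, 5), pa), 100)
  expect_error(burden(c(0, 0, 0, 0), pa), "all-zero")
  pc <- cml_parameters()
  expect_equal(burden(c(0, pc$K_Y / 2, 0), pc), 50)
})

test_that("simulation respects the horizon and its tolerance is converged", {
  co <- fixture_cohort("AML", 6)
  r <- co$records[[1]]
  expect_error(simulate_course(r$params, r$schedule, c(1, 25)), "horizon")

  grid <- dense_grid("AML")
  a <- simulate_course(r$params, r$schedule, grid, rtol = 1e-8)
  b <- simulate_course(r$params, r$schedule, grid, rtol = 5e-9)
  expect_lt(max(abs(b$burden_pct - a$burden_pct) / b$burden_pct), 1e-3)

  # independent stiff-capable reference integrator agrees
  sub <- grid[seq(1, length(grid), by = 10)]
  d1 <- simulate_course(r$params, r$schedule, sub, engine = "rk45")
  d2 <- simulate_course(r$params, r$schedule, sub, engine = "lsoda")
  expect_equal(d1$burden_pct, d2$burden_pct, tolerance = 1e-4)

  # CML reference-integrator agreement, including the half-dose scheme
  cc <- fixture_cohort("CML", 4)
  rc <- cc$records[[1]]
  sch <- cml_schedule(rc$schedule$t_stop, rc$schedule$t_stop - 12)
  tt <- seq(0, rc$schedule$t_stop + 24, by = 6)
  e1 <- simulate_course(rc$params, sch, tt, engine = "rk45")
  e2 <- simulate_course(rc$params, sch, tt, engine = "lsoda")
  expect_equal(e1$burden_pct, e2$burden_pct, tolerance = 1e-4)
})

test_that("states stay nonnegative and the active pool respects its capacity", {
  co <- fixture_cohort("AML", 10)
  for (r in co$records[1:10]) {
    st <- relapsim:::simulate_states(r$params, r$schedule, dense_grid("AML"))
    expect_true(all(st > -1e-4))
    expect_true(all(st[, 2] + st[, 4] <= r$params$K_A * 1.01))
  }
})

test_that("stronger TKI dosing yields pointwise lower leukemic burden", {
  cc <- fixture_cohort("CML", 10)
  for (r in cc$records) {
    tt <- seq(0, r$schedule$t_stop, by = 3)
    p_hi <- r$params
    p_hi$e_TKI <- p_hi$e_TKI * 1.5
    lo <- relapsim:::simulate_states(r$params, r$schedule, tt)[, 2]
    hi <- relapsim:::simulate_states(p_hi, r$schedule, tt)[, 2]
    expect_true(all(hi <= lo * (1 + 1e-6) + 1e-9))
  }
})

test_that("relapse labeling implements the threshold rules", {
  sch <- fixture_schedule_aml()
  mk <- function(b, t = seq_along(b)) new_trajectory("x", "AML", "D", t, b)
  # drops to 0.01%, rises to 2% at month 15 -> relapse
  expect_true(label_relapse(mk(c(50, 5, 0.5, 0.01, 0.01, 0.5, 2, 2),
                               t = c(1, 2, 3, 5, 9, 12, 15, 20)),
                            "AML", sch))
  # never exceeds 1% again -> no relapse
  expect_false(label_relapse(mk(c(50, 0.5, 0.01, 0.02), t = c(1, 3, 9, 20)),
                             "AML", sch))
  # never below 1% -> error (excluded upstream)
  expect_error(label_relapse(mk(c(50, 20, 10, 5), t = c(1, 5, 9, 20)),
                             "AML", sch), "no remission")
  # identically at the floor -> false
  expect_false(label_relapse(mk(rep(1e-6, 5), t = 1:5), "AML", sch))

  scml <- fixture_schedule_cml(60)
  mkc <- function(b, t) new_trajectory("y", "CML", "D", t, b)
  # single isolated exceedance flanked by low values: span < 1 month
  tt <- c(50, 55, 60, 61, 62, 63, 64)
  expect_false(label_relapse(mkc(c(0.01, 0.01, 0.01, 0.05, 0.15, 0.05, 0.05),
                                 tt), "CML", scml))
  # two consecutive monthly exceedances: span >= 1 month
  expect_true(label_relapse(mkc(c(0.01, 0.01, 0.01, 0.05, 0.15, 0.2, 0.05),
                                tt), "CML", scml))
  # exceedance before cessation does not count
  expect_false(label_relapse(mkc(c(5, 0.5, 0.01, 0.02, 0.02, 0.02, 0.02),
                                 tt), "CML", scml))

  # labeling is a pure function
  d <- fixture_cohort("AML", 6)$records[[2]]
  expect_identical(label_relapse(d$dense, "AML", d$schedule),
                   label_relapse(d$dense, "AML", d$schedule))
})
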