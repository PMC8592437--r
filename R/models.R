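# Disease models: right-hand sides, forward simulation, burden observable,
# relapse labeling.

# AML state: (Q_H, A_H, Q_L, A_L), time in days.
# CML state: (X, Y, Z), time in months.

BURDEN_FLOOR <- 1e-6   # percent; keeps log10(burden) defined
AML_HORIZON_MONTHS <- 24
CML_POST_STOP_MONTHS <- 120
AML_WINDOW_MONTHS <- 9

#' AML model right-hand side
#'
#' Healthy (H) and leukemic (L) stem cells exchange between a shared
#' quiescent niche (capacity `K_Q`) and a shared active niche (`K_A`);
#' activation is gated by free space in the active niche, deactivation by
#' free space in the quiescent niche. Active cells proliferate
#' logistically, differentiate out of the pool, and are killed by
#' chemotherapy while a cycle is running.
#'
#' @param state numeric 4-vector `(Q_H, A_H, Q_L, A_L)`, non-negative.
#' @param t time in days.
#' @param params [aml_parameters()].
#' @param schedule AML [treatment_schedule][aml_schedule()].
#' @return derivative 4-vector (cells per day).
#' @export
aml_rhs <- function(state, t, params, schedule) {
  if (any(!is.finite(state))) stop("non-finite state: simulation blow-up")
  u <- dose_at(schedule, t)
  occQ <- 1 - (state[1] + state[3]) / params$K_Q
  occA <- 1 - (state[2] + state[4]) / params$K_A
  fH <- params$t_QA_H * state[1] * occA - params$t_AQ_H * state[2] * occQ
  fL <- params$t_QA_L * state[3] * occA - params$t_AQ_L * state[4] * occQ
  c(-fH,
    fH + params$p_H * state[2] * occA - params$d_H * state[2] - params$c * u * state[2],
    -fL,
    fL + params$p_L * state[4] * occA - params$d_L * state[4] - params$c * u * state[4])
}

#' CML model right-hand side
#'
#' Quiescent (`X`) and active (`Y`) leukemic cells exchange linearly; active
#' cells grow logistically, are killed by dose-dependent TKI action and by
#' immune effector cells `Z`; immune cells are recruited through an immune
#' window response maximal at `Y = sqrt(K_Z)`.
#'
#' @param state numeric 3-vector `(X, Y, Z)`, non-negative.
#' @param t time in months.
#' @param params [cml_parameters()].
#' @param schedule CML [treatment_schedule][cml_schedule()].
#' @return derivative 3-vector (cells per month).
#' @export
cml_rhs <- function(state, t, params, schedule) {
  if (any(!is.finite(state))) stop("non-finite state: simulation blow-up")
  dose <- dose_at(schedule, t)
  X <- state[1]; Y <- state[2]; Z <- state[3]
  flow <- params$p_XY * X - params$p_YX * Y
  c(-flow,
    flow + params$p_Y * Y * (1 - Y / params$K_Y) -
      params$e_TKI * dose * Y - params$m * Y * Z,
    params$r_Z - params$a * Z + params$p_Z * Z * Y / (params$K_Z + Y^2))
}

#' Leukemic burden observable (percent)
#'
#' AML: `100 * (Q_L + A_L) / (Q_H + A_H + Q_L + A_L)`, the leukemic fraction
#' of the stem-cell pool, matching the scale of clinical NPM1-mut/ABL
#' ratios. CML: `100 * Y / K_Y`, active leukemic cells relative to carrying
#' capacity, matching BCR-ABL1/ABL1 ratios. Values are floored at a small
#' positive level (default `1e-6` percent) so the log10 scale is defined.
#'
#' @param state model state vector, or a matrix with one state per row.
#' @param params parameter object (determines the disease).
#' @param floor lower floor in percent.
#' @return burden in percent.
#' @export
burden <- function(state, params, floor = BURDEN_FLOOR) {
  disease <- disease_of(params)
  if (is.null(dim(state))) state <- matrix(state, nrow = 1)
  if (any(state < -1e-6 * max(abs(state), 1))) {
    state[state < 0] <- 0
  }
  b <- if (disease == "AML") {
    tot <- rowSums(state)
    if (any(tot <= 0)) stop("all-zero AML state: burden undefined")
    100 * (state[, 3] + state[, 4]) / tot
  } else {
    100 * state[, 2] / params$K_Y
  }
  pmax(b, floor)
}

aml_initial_state <- function(params) {
  # diagnosis convention: active niche dominated by the leukemic clone,
  # healthy cells largely sheltered in quiescence
  c(Q_H = 0.2 * params$K_Q, A_H = 0.1 * params$K_A,
    Q_L = 0.005 * params$K_Q, A_L = 0.9 * params$K_A)
}

cml_initial_state <- function(params) {
  c(X = params$X0, Y = params$Y0, Z = params$Z0)
}

new_trajectory <- function(patient_id, disease, variant, time_months,
                           burden_pct, censored = rep(FALSE, length(time_months))) {
  if (length(time_months) != length(burden_pct) ||
      length(time_months) != length(censored))
    stop("times, values and censoring flags must have equal length")
  if (is.unsorted(time_months, strictly = TRUE))
    stop("trajectory times must be strictly increasing")
  if (any(burden_pct <= 0)) stop("burden values must be > 0")
  structure(data.frame(patient_id = patient_id, disease = disease,
                       variant = variant, time_months = time_months,
                       burden_pct = burden_pct, censored = censored,
                       stringsAsFactors = FALSE),
            class = c("trajectory", "data.frame"))
}

#' Simulate a dense, noise-free remission time course (variant D)
#'
#' Integrates the disease model with a compiled adaptive Runge-Kutta 4(5)
#' scheme (dose discontinuities handled exactly by segment-wise integration)
#' and evaluates the burden observable at the requested grid. The slower
#' `deSolve::lsoda` path integrates the R-level right-hand sides and serves
#' as an independent numerical cross-check.
#'
#' @param params parameter object.
#' @param schedule matching treatment schedule.
#' @param grid_months output time points in months, within the simulated
#'   horizon (AML: 24 months; CML: cessation + 120 months).
#' @param patient_id id stored in the trajectory.
#' @param rtol relative integration tolerance.
#' @param engine `"rk45"` (compiled) or `"lsoda"` (deSolve reference).
#' @return a trajectory data frame (variant `"D"`, no censoring).
#' @export
simulate_course <- function(params, schedule, grid_months,
                            patient_id = "p1", rtol = 1e-8,
                            engine = c("rk45", "lsoda")) {
  engine <- match.arg(engine)
  disease <- disease_of(params)
  if (disease != schedule$disease) stop("schedule/parameter disease mismatch")
  if (any(grid_months < 0)) stop("grid must be non-negative")
  horizon <- if (disease == "AML") AML_HORIZON_MONTHS else
    schedule$t_stop + CML_POST_STOP_MONTHS
  if (max(grid_months) > horizon + 1e-9)
    stop(sprintf("grid exceeds the %s simulation horizon (%g months)",
                 disease, horizon))
  states <- simulate_states(params, schedule, grid_months, rtol, engine)
  new_trajectory(patient_id, disease, "D", grid_months,
                 burden(states, params))
}

# state matrix at grid_months (rows = time points); state0 overrides the
# disease's diagnosis convention
simulate_states <- function(params, schedule, grid_months, rtol = 1e-8,
                            engine = "rk45", state0 = NULL) {
  disease <- disease_of(params)
  seg <- dose_segments(schedule)
  if (disease == "AML") {
    times <- months_to_days(grid_months)
    y0 <- state0 %||% aml_initial_state(params)
    if (engine == "rk45") {
      .sim_aml_cpp(aml_rate_vector(params), y0, times, seg$t, seg$v,
                   rtol, 1e-8)
    } else {
      lsoda_states(y0, times, seg,
                   function(t, y, u) aml_rhs_core(y, params, u), rtol)
    }
  } else {
    y0 <- state0 %||% cml_initial_state(params)
    if (engine == "rk45") {
      .sim_cml_cpp(cml_rate_vector(params), y0, grid_months, seg$t, seg$v,
                   rtol, 1e-10)
    } else {
      lsoda_states(y0, grid_months, seg,
                   function(t, y, u) cml_rhs_core(y, params, u), rtol)
    }
  }
}

aml_rhs_core <- function(y, p, u) {
  occQ <- 1 - (y[1] + y[3]) / p$K_Q
  occA <- 1 - (y[2] + y[4]) / p$K_A
  fH <- p$t_QA_H * y[1] * occA - p$t_AQ_H * y[2] * occQ
  fL <- p$t_QA_L * y[3] * occA - p$t_AQ_L * y[4] * occQ
  c(-fH, fH + p$p_H * y[2] * occA - p$d_H * y[2] - p$c * u * y[2],
    -fL, fL + p$p_L * y[4] * occA - p$d_L * y[4] - p$c * u * y[4])
}

cml_rhs_core <- function(y, p, dose) {
  flow <- p$p_XY * y[1] - p$p_YX * y[2]
  c(-flow,
    flow + p$p_Y * y[2] * (1 - y[2] / p$K_Y) - p$e_TKI * dose * y[2] -
      p$m * y[2] * y[3],
    p$r_Z - p$a * y[3] + p$p_Z * y[3] * y[2] / (p$K_Z + y[2]^2))
}

# deSolve reference integration, segment-wise across dose breakpoints
lsoda_states <- function(y0, times, seg, rhs, rtol) {
  breaks <- sort(unique(c(0, seg$t[seg$t > 0], times)))
  out <- matrix(NA_real_, length(times), length(y0))
  y <- y0
  t <- 0
  if (any(times <= 0)) out[times <= 0, ] <- matrix(y0, sum(times <= 0),
                                                   length(y0), byrow = TRUE)
  for (te in breaks[breaks > 0]) {
    tm <- (t + te) / 2
    u <- seg$v[max(1, findInterval(tm, seg$t))]
    sol <- deSolve::lsoda(y, c(t, te),
                          function(tt, yy, parms) list(rhs(tt, yy, u)),
                          parms = NULL, rtol = rtol, atol = 1e-10)
    y <- as.numeric(sol[nrow(sol), -1])
    t <- te
    hit <- which(abs(times - te) < 1e-9)
    if (length(hit)) out[hit, ] <- matrix(y, length(hit), length(y0), byrow = TRUE)
  }
  out
}

#' Ground-truth relapse / molecular-recurrence label
#'
#' AML: relapse if the burden, after first falling below the 1 percent
#' remission threshold, exceeds 1 percent at any grid point within 24 months
#' of treatment start; a trajectory that never reaches remission raises an
#' error (such patients are excluded upstream). CML: molecular recurrence if
#' the burden exceeds 0.1 percent (MR3 threshold) for a contiguous span of
#' at least one month within ten years after therapy cessation.
#'
#' @param dense noise-free dense trajectory (variant D).
#' @param disease `"AML"` or `"CML"`.
#' @param schedule the patient's treatment schedule.
#' @return logical relapse label.
#' @export
label_relapse <- function(dense, disease = dense$disease[1], schedule) {
  tt <- dense$time_months
  bb <- dense$burden_pct
  if (disease == "AML") {
    below <- which(bb < 1)
    if (!length(below)) stop("no remission: AML trajectory never below 1%")
    first <- below[1]
    idx <- which(tt <= AML_HORIZON_MONTHS + 1e-9)
    any(bb[idx] > 1 & idx > first)
  } else {
    idx <- which(tt > schedule$t_stop + 1e-9 &
                   tt <= schedule$t_stop + CML_POST_STOP_MONTHS + 1e-9)
    if (!length(idx)) return(FALSE)
    exc <- bb[idx] > 0.1
    r <- rle(exc)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      span <- tt[idx[ends[k]]] - tt[idx[starts[k]]]
      if (span >= 1 - 1e-9) return(TRUE)
    }
    FALSE
  }
}

# dense simulation grids (months)
dense_grid <- function(disease, schedule = NULL) {
  if (disease == "AML") {
    # weekly monitoring from one week after treatment start to month 24;
    # this yields 39 in-window points over the 9-month input window
    days_to_months(seq(7, months_to_days(AML_HORIZON_MONTHS) - 1e-9, by = 7))
  } else {
    seq(0, floor(schedule$t_stop) + CML_POST_STOP_MONTHS, by = 1)
  }
}

# input window end in months
input_window_end <- function(disease, schedule) {
  if (disease == "AML") AML_WINDOW_MONTHS else schedule$t_stop
}
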