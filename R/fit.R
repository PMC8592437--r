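# Mechanistic-model predictor: refit the patient-specific parameters to the
# input window (sum of squared log10 residuals, one-sided for censored
# points), then simulate forward and label the simulated course.

# observations for fitting: times (months), log10 values, censoring flags
mm_observations <- function(input) {
  list(t = input$time_months, y = log10(input$burden_pct),
       cens = input$censored)
}

# fast objective: simulate at the observation times and accumulate squared
# log10 residuals; censored points only penalize simulated values above the
# detection limit
mm_objective_fn <- function(obs, disease, schedule, base_params, free_names,
                            lod, rtol = 1e-5) {
  seg <- dose_segments(schedule)
  loglod <- log10(lod)
  if (disease == "AML") {
    times <- months_to_days(obs$t)
    function(theta_log) {
      p <- base_params
      for (j in seq_along(free_names)) p[[free_names[j]]] <- exp(theta_log[j])
      st <- tryCatch(
        .sim_aml_cpp(aml_rate_vector(p), aml_initial_state(p), times,
                     seg$t, seg$v, rtol, 1e-4),
        error = function(e) NULL)
      if (is.null(st)) return(1e10)
      ysim <- log10(burden(st, p))
      sum(ifelse(obs$cens, pmax(0, ysim - loglod), ysim - obs$y)^2)
    }
  } else {
    function(theta_log) {
      p <- base_params
      for (j in seq_along(free_names)) p[[free_names[j]]] <- exp(theta_log[j])
      st <- tryCatch(
        .sim_cml_cpp(cml_rate_vector(p), cml_initial_state(p), obs$t,
                     seg$t, seg$v, rtol, 1e-10),
        error = function(e) NULL)
      if (is.null(st)) return(1e10)
      ysim <- log10(burden(st, p))
      sum(ifelse(obs$cens, pmax(0, ysim - loglod), ysim - obs$y)^2)
    }
  }
}

# log-scale box bounds for the free parameters, from the prior's span
mm_bounds <- function(prior) {
  lo <- vapply(prior$free_names, function(nm) min(prior$base[[nm]]), 0) * 0.5
  hi <- vapply(prior$free_names, function(nm) max(prior$base[[nm]]), 0) * 2
  list(lo = log(lo), hi = log(hi))
}

#' Refit the patient-specific model parameters to an input window
#'
#' Minimizes the sum of squared residuals between the simulated and the
#' measured log10 burden over the patient-specific parameters. Censored
#' points contribute one-sidedly (`max(0, log10 sim - log10 lod)^2`). AML
#' (2 free parameters): bounded quasi-Newton local optimization (L-BFGS-B on
#' the log scale) restarted from prior-sampled starting points. CML (7 free
#' parameters): a generational genetic algorithm (population 50, 40
#' generations, tournament selection, Gaussian mutation, elitism) followed
#' by a local polish of the best individual.
#'
#' @param input trajectory rows inside the input window.
#' @param disease disease tag.
#' @param schedule the patient's schedule.
#' @param prior [parameter_prior()] supplying global parameter values,
#'   starting points and box bounds.
#' @param seed optional seed (restart draws, GA randomness).
#' @param restarts number of local restarts (AML).
#' @param lod detection limit used for censored residuals.
#' @param control GA settings: `pop`, `generations`, `mut_sd`, `mut_prob`,
#'   `tournament`, `elite`.
#' @return object of class `fit_result`: `par` (named fitted values),
#'   `objective`, `converged`, `restarts`, `evaluations`.
#' @export
fit_mechanistic <- function(input, disease, schedule, prior, seed = NULL,
                            restarts = 5, lod = 0.01, control = list()) {
  if (disease == "AML" && nrow(input) < 2)
    stop("AML fitting needs at least 2 points")
  if (disease == "CML" && nrow(input) < 4)
    stop("CML fitting needs at least 4 points")
  obs <- mm_observations(input)
  base <- if (disease == "AML") {
    do.call(aml_parameters, c(as.list(vapply(
      .AML_PAR_NAMES, function(nm) median(prior$base[[nm]]), 0)),
      list(free_names = prior$free_names)))
  } else {
    do.call(cml_parameters, c(as.list(vapply(
      .CML_PAR_NAMES, function(nm) median(prior$base[[nm]]), 0)),
      list(free_names = prior$free_names)))
  }
  fn <- mm_objective_fn(obs, disease, schedule, base, prior$free_names, lod)
  b <- mm_bounds(prior)
  with_seed(seed, {
    if (disease == "AML") mm_fit_local(fn, prior, b, restarts)
    else mm_fit_ga(fn, prior, b, control)
  })
}

mm_fit_local <- function(fn, prior, b, restarts) {
  starts <- list(log(vapply(prior$free_names,
                            function(nm) median(prior$base[[nm]]), 0)))
  if (restarts > 1) {
    ps <- sample_parameters(prior, restarts - 1)
    for (p in ps) starts <- c(starts, list(log(unlist(p[prior$free_names]))))
  }
  best <- NULL
  conv <- FALSE
  nev <- 0
  for (s in starts) {
    s <- pmin(pmax(s, b$lo), b$hi)
    fit <- tryCatch(
      optim(s, fn, method = "L-BFGS-B", lower = b$lo, upper = b$hi,
            control = list(maxit = 100, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    nev <- nev + fit$counts[1]
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  structure(list(par = setNames(exp(best$par), prior$free_names),
                 objective = best$value, converged = conv,
                 restarts = restarts, evaluations = unname(nev)),
            class = "fit_result")
}

mm_fit_ga <- function(fn, prior, b, control) {
  ctl <- modifyList(list(pop = 50, generations = 40, mut_sd = 0.15,
                         mut_prob = 0.35, tournament = 3, elite = 2), control)
  d <- length(b$lo)
  span <- b$hi - b$lo
  pop <- t(replicate(ctl$pop, b$lo + runif(d) * span))
  fit <- apply(pop, 1, fn)
  nev <- ctl$pop
  for (g in seq_len(ctl$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(ctl$elite)], , drop = FALSE]
    while (nrow(newpop) < ctl$pop) {
      pick <- function() {
        cand <- sample(ctl$pop, ctl$tournament)
        pop[cand[which.min(fit[cand])], ]
      }
      p1 <- pick(); p2 <- pick()
      cross <- runif(d) < 0.5
      child <- ifelse(cross, p1, p2)
      mut <- runif(d) < ctl$mut_prob
      child[mut] <- child[mut] + rnorm(sum(mut), 0, ctl$mut_sd * span[mut])
      child <- pmin(pmax(child, b$lo), b$hi)
      newpop <- rbind(newpop, child)
    }
    keep_fit <- fit[ord[seq_len(ctl$elite)]]
    newfit <- apply(newpop[-seq_len(ctl$elite), , drop = FALSE], 1, fn)
    nev <- nev + length(newfit)
    pop <- newpop
    fit <- c(keep_fit, newfit)
  }
  i <- which.min(fit)
  polish <- tryCatch(
    optim(pop[i, ], fn, method = "L-BFGS-B", lower = b$lo, upper = b$hi,
          control = list(maxit = 100, factr = 1e5)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= fit[i]) {
    par <- polish$par
    val <- polish$value
    conv <- polish$convergence == 0
    nev <- nev + polish$counts[1]
  } else {
    par <- pop[i, ]
    val <- fit[i]
    conv <- FALSE
  }
  structure(list(par = setNames(exp(par), prior$free_names),
                 objective = val, converged = conv, restarts = 1,
                 evaluations = unname(nev)),
            class = "fit_result")
}

#' Mechanistic relapse prediction for one patient
#'
#' Refits the patient-specific parameters to the input window, simulates the
#' fitted model over the full horizon and applies the ground-truth labeling
#' rule to the simulated dense course. The score is hard (0/1): a simulated
#' course either crosses the relapse threshold or it does not. An AML fit
#' whose simulated course never reaches remission is predicted as relapse
#' (refractory course).
#'
#' @param input input-window trajectory rows.
#' @param disease,schedule patient context.
#' @param prior [parameter_prior()].
#' @param seed optional seed.
#' @param ... passed to [fit_mechanistic()].
#' @return list: `prediction` (logical), `score`, `fit` (the `fit_result`).
#' @export
predict_mm <- function(input, disease, schedule, prior, seed = NULL, ...) {
  fit <- fit_mechanistic(input, disease, schedule, prior, seed = seed, ...)
  base_names <- if (disease == "AML") .AML_PAR_NAMES else .CML_PAR_NAMES
  ctor <- if (disease == "AML") aml_parameters else cml_parameters
  params <- do.call(ctor, c(as.list(vapply(
    base_names, function(nm) median(prior$base[[nm]]), 0)),
    list(free_names = prior$free_names)))
  params <- set_parameters(params, fit$par)
  dense <- simulate_course(params, schedule, dense_grid(disease, schedule),
                           patient_id = "mm-forecast")
  lab <- tryCatch(label_relapse(dense, disease, schedule),
                  error = function(e) TRUE)  # never-remitting forecast
  list(prediction = lab, score = as.numeric(lab), fit = fit)
}
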