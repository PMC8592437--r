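# Synthetic cohort generation: parameter priors standing in for the
# empirical patient fits, cessation-time sampling, forward simulation,
# remission filtering and ground-truth labeling.

#' Default AML base parameter table
#'
#' Reference parameter sets emulating a fitted patient population. The nine
#' global parameters are identical across rows (they encode the shared
#' treatment dynamics); the two patient-specific parameters -- leukemic
#' proliferation `p_L` and leukemic quiescence exit `t_QA_L` -- span a grid
#' of regrowth speeds and reservoir kinetics wide enough to produce both
#' relapsing and non-relapsing remission courses.
#'
#' @return data frame with one row per reference parameter set.
#' @export
aml_base_table <- function() {
  g <- expand.grid(p_L = c(0.08, 0.10, 0.12, 0.14, 0.15, 0.16, 0.18),
                   t_QA_L = c(0.05, 0.09, 0.16, 0.28))
  # fast regrowth combined with a slow quiescence exit yields refractory
  # courses that the remission filter would reject; not part of the prior
  g <- g[!(g$p_L >= 0.15 & g$t_QA_L < 0.06), ]
  data.frame(t_QA_H = 0.02, t_AQ_H = 0.05, p_H = 0.15, d_H = 0.05,
             t_QA_L = g$t_QA_L, t_AQ_L = 0.002, p_L = g$p_L, d_L = 0.05,
             K_Q = 1e5, K_A = 1e6, c = 1.2)
}

#' Default CML base parameter table
#'
#' Thirty reference parameter sets for the CML model. The six global
#' quantities (logistic growth, immune production/decay, initial reservoir
#' and tumour load) are shared; the seven patient-specific parameters vary
#' across rows with realistic mutual correlations, generated once from two
#' latent axes -- overall TKI response strength and immune competence --
#' plus independent reservoir kinetics. Stronger responders (higher
#' `e_TKI`) tend to have more competent immune control (higher `m`, `p_Z`),
#' which is what makes the half-dose perturbation informative.
#'
#' @return data frame with one row per reference parameter set.
#' @export
cml_base_table <- function() {
  n <- 30
  # fixed latent construction (quasi-uniform van der Corput sequences) so the
  # table is deterministic and inspectable
  vdc <- function(n, base) {
    sapply(seq_len(n), function(i) {
      x <- 0; f <- 1 / base; k <- i
      while (k > 0) { x <- x + f * (k %% base); k <- k %/% base; f <- f / base }
      x
    })
  }
  u_resp <- vdc(n, 2)          # TKI response axis
  u_imm <- 0.6 * u_resp + 0.4 * vdc(n, 3)   # immune axis, correlated
  u_res <- vdc(n, 5)           # reservoir kinetics axis
  u_misc <- vdc(n, 7)
  data.frame(
    p_XY = 0.01 * 8^u_res,                 # 0.01 .. 0.08 /month
    p_YX = 0.002 * 10^(0.8 * u_res + 0.2 * u_misc),  # correlated with p_XY
    p_Y = 1.0, K_Y = 1e6,
    e_TKI = 1.6 + 2.4 * u_resp,            # 1.6 .. 4.0 /month
    m = 0.001 * 8^u_imm,                  # 0.001 .. 0.008 /cell/month
    p_Z = 20 + 70 * u_imm,                 # 20 .. 90 /month
    K_Z = 2e3 * 25^u_misc,                 # window centre 45 .. 224 cells
    r_Z = 20, a = 0.2,
    X0 = 1e4, Y0 = 1e6,
    Z0 = 50 + 150 * (0.5 * u_imm + 0.5 * u_misc)
  )
}

#' Parameter prior emulating the empirical fit population
#'
#' @param disease `"AML"` or `"CML"`.
#' @param base reference parameter table; defaults ship with the package.
#' @param jitter_sd named relative (log-normal) jitter SD per parameter;
#'   defaults: 0.10 for the patient-specific parameters, 0 for the global
#'   ones (they are population constants).
#' @param rank_cor rank-correlation matrix over the free parameters (CML
#'   only); default: Spearman correlation of the base table.
#' @param free_names patient-specific parameter names.
#' @return object of class `parameter_prior`.
#' @export
parameter_prior <- function(disease = c("AML", "CML"), base = NULL,
                            jitter_sd = NULL, rank_cor = NULL,
                            free_names = NULL) {
  disease <- match.arg(disease)
  all_names <- if (disease == "AML") .AML_PAR_NAMES else .CML_PAR_NAMES
  free_names <- free_names %||%
    (if (disease == "AML") .AML_FREE_DEFAULT else .CML_FREE_DEFAULT)
  base <- base %||% (if (disease == "AML") aml_base_table() else cml_base_table())
  if (!nrow(base)) stop("prior base table must be non-empty")
  if (!all(all_names %in% names(base)))
    stop("base table must contain all model parameters")
  if (is.null(jitter_sd)) {
    jitter_sd <- setNames(rep(0, length(all_names)), all_names)
    jitter_sd[free_names] <- 0.10
  }
  if (any(jitter_sd < 0)) stop("jitter SD must be >= 0")
  if (disease == "CML") {
    rank_cor <- rank_cor %||% cor(base[free_names], method = "spearman")
    check_corr_matrix(rank_cor, length(free_names))
  }
  structure(list(disease = disease, base = base, jitter_sd = jitter_sd,
                 rank_cor = rank_cor, free_names = free_names),
            class = "parameter_prior")
}

check_corr_matrix <- function(R, p) {
  if (!is.matrix(R) || nrow(R) != p || ncol(R) != p)
    stop("correlation matrix has wrong dimensions")
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation matrix needs unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation matrix must be positive semi-definite")
  invisible(TRUE)
}

#' Sample patient-specific parameter sets from a prior
#'
#' AML: draws base rows with replacement and multiplies each parameter by
#' an independent log-normal jitter `exp(N(0, sd^2))` (relative jitter keeps
#' rates positive and prevents identical duplicates). CML: samples the free
#' parameters from a Gaussian copula whose marginals are the interpolated
#' empirical quantiles of the base table and whose rank correlations match
#' the prior.
#'
#' @param prior a [parameter_prior()].
#' @param n number of parameter sets.
#' @param seed optional seed.
#' @return list of `aml_parameters` / `cml_parameters` objects.
#' @export
sample_parameters <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "parameter_prior"))
  with_seed(seed, {
    if (prior$disease == "AML") sample_parameters_aml(prior, n)
    else sample_parameters_cml(prior, n)
  })
}

sample_parameters_aml <- function(prior, n) {
  rows <- sample(nrow(prior$base), n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- unlist(prior$base[rows[i], .AML_PAR_NAMES])
    jit <- exp(rnorm(length(v), 0, prior$jitter_sd[.AML_PAR_NAMES]))
    out[[i]] <- do.call(aml_parameters,
                        c(as.list(v * jit), list(free_names = prior$free_names)))
  }
  check_distinct(out, prior$free_names)
  out
}

sample_parameters_cml <- function(prior, n) {
  fn <- prior$free_names
  # Spearman rank correlation -> Gaussian copula correlation
  R <- 2 * sin(pi * prior$rank_cor / 6)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {  # ridge for numerically semi-definite inputs
    R <- R + diag(1e-8 - min(ev$values), nrow(R))
    R <- stats::cov2cor(R)
  }
  Z <- MASS::mvrnorm(n, mu = rep(0, length(fn)), Sigma = R)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  U <- pnorm(Z)
  fixed <- unlist(prior$base[1, setdiff(.CML_PAR_NAMES, fn)])
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- fixed
    for (j in seq_along(fn))
      v[fn[j]] <- as.numeric(quantile(prior$base[[fn[j]]], U[i, j], type = 7))
    out[[i]] <- do.call(cml_parameters,
                        c(as.list(v[.CML_PAR_NAMES]),
                          list(free_names = fn)))
  }
  check_distinct(out, fn)
  out
}

check_distinct <- function(params, free_names) {
  if (length(params) < 2) return(invisible(TRUE))
  key <- vapply(params, function(p)
    paste(signif(unlist(p[free_names]), 12), collapse = "|"), "")
  if (anyDuplicated(key)) stop("sampled parameter sets contain duplicates")
  invisible(TRUE)
}

#' Sample TKI cessation times
#'
#' Truncated-normal sampler standing in for the kernel-density estimate of
#' observed cessation times: the pre-truncation mean and SD are calibrated
#' (via the closed-form truncated-normal moments) so that the realized
#' truncated distribution has the target mean and SD.
#'
#' @param n number of draws.
#' @param mean,sd target mean and SD of cessation time (months).
#' @param lower truncation bound (months).
#' @param seed optional seed.
#' @return numeric vector of cessation times (months).
#' @export
sample_cessation <- function(n, mean = 92, sd = 28.2, lower = 24, seed = NULL) {
  ms <- trunc_normal_calibrate(mean, sd, lower)
  with_seed(seed, {
    plo <- pnorm((lower - ms[1]) / ms[2])
    u <- runif(n, plo, 1)
    ms[1] + ms[2] * qnorm(u)
  })
}

# truncated-normal moments for lower truncation at a = (L - mu)/sigma
trunc_normal_moments <- function(mu, sigma, L) {
  a <- (L - mu) / sigma
  lam <- dnorm(a) / (1 - pnorm(a))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

trunc_normal_calibrate <- function(target_mean, target_sd, lower) {
  obj <- function(th) {
    mo <- trunc_normal_moments(th[1], exp(th[2]), lower)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

#' Cohort configuration
#'
#' @param disease `"AML"` or `"CML"`.
#' @param n_patients number of included patients to generate.
#' @param seed master seed for the cohort.
#' @param prior optional [parameter_prior()]; default prior of the disease.
#' @param cessation CML cessation sampler settings
#'   (`mean`, `sd`, `lower` in months).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(disease = c("AML", "CML"), n_patients = 100,
                          seed = 1, prior = NULL,
                          cessation = list(mean = 92, sd = 28.2, lower = 24)) {
  disease <- match.arg(disease)
  if (n_patients < 1) stop("n_patients must be >= 1")
  structure(list(disease = disease, n_patients = as.integer(n_patients),
                 seed = as.integer(seed),
                 prior = prior %||% parameter_prior(disease),
                 cessation = cessation),
            class = "cohort_config")
}

#' Generate a labeled synthetic cohort
#'
#' Samples parameters and treatment schedules, simulates each patient's
#' dense noise-free trajectory (AML: weekly to month 24; CML: monthly to
#' cessation + 120 months), applies the remission filter (AML patients whose
#' burden never falls below 1 percent within the 9-month input window are
#' excluded and resampled) and attaches the ground-truth relapse label.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: list with `records` (patient records),
#'   `config`, and `n_excluded`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  disease <- config$disease
  records <- vector("list", n)
  got <- 0L
  attempt <- 0L
  excluded <- 0L
  while (got < n) {
    attempt <- attempt + 1L
    if (attempt > 10L * n)
      stop("remission filter rejected too many patients (",
           excluded, " of ", attempt - 1L,
           "); the prior produces too few remissions")
    params <- sample_parameters(config$prior, 1,
                                seed = derive_seed(config$seed, paste0("par", attempt)))[[1]]
    schedule <- sample_schedule(disease, 1,
                                seed = derive_seed(config$seed, paste0("sch", attempt)),
                                cessation = config$cessation)
    id <- sprintf("%s-%04d", disease, got + 1L)
    dense <- simulate_course(params, schedule, dense_grid(disease, schedule),
                             patient_id = id)
    if (disease == "AML") {
      win <- dense$burden_pct[dense$time_months <= AML_WINDOW_MONTHS + 1e-9]
      if (min(win) >= 1) {
        excluded <- excluded + 1L
        next
      }
    }
    rec <- structure(list(id = id, disease = disease, params = params,
                          schedule = schedule, dense = dense,
                          relapse = label_relapse(dense, disease, schedule),
                          excluded = FALSE),
                     class = "patient_record")
    got <- got + 1L
    records[[got]] <- rec
  }
  structure(list(records = records, config = config, n_excluded = excluded),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cohort> %s, %d patients (%d excluded by remission filter), relapse fraction %.2f\n",
              x$config$disease, length(x$records), x$n_excluded, mean(lab)))
  invisible(x)
}

#' Relapse labels of a cohort
#' @param cohort a [generate_cohort()] result.
#' @return logical vector.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$records, function(r) r$relapse, logical(1))
}
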