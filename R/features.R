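# Explicit time-course features for the logistic-regression predictor.
# All fits work on log10 burden; censored values enter at the detection
# limit (that is how they are stored).

#' AML time-course features
#'
#' Five features describing the treatment response: `y0`, the fitted log10
#' burden at diagnosis; `a` and `b`, the shared slopes during and between
#' chemotherapy cycles from a continuous segmented regression with
#' breakpoints at the cycle boundaries; `alpha`, the overall elimination
#' slope (ordinary least squares over all points up to treatment end,
#' fitted separately); and `n`, the lowest measured log10 burden after
#' treatment end.
#'
#' The segmented model is linear in `(y0, a, b)`: the fitted value at time
#' `t` is `y0 + a * g_a(t) + b * g_b(t)`, where `g_a(t)` is the cumulative
#' time spent inside cycles up to `t` and `g_b(t)` the cumulative time
#' outside them; continuity at every breakpoint is automatic and one common
#' slope is shared across all cycles (identifiable from as few as three
#' points). If the design is singular (all points in one regime) both
#' slopes collapse to the single-line slope.
#'
#' @param input trajectory rows inside the input window.
#' @param schedule the patient's AML schedule.
#' @return named numeric vector `(alpha, n, y0, a, b)`, slopes in
#'   log10 percent per month.
#' @export
aml_features <- function(input, schedule) {
  if (nrow(input) < 3) stop("insufficient data for segmented regression")
  t <- input$time_months
  y <- log10(input$burden_pct)
  cyc <- days_to_months(schedule$cycles)
  ga <- vapply(t, function(ti)
    sum(pmax(0, pmin(ti, cyc[, 2]) - cyc[, 1])), 0)
  gb <- t - ga
  fit <- lm(y ~ ga + gb)
  cf <- coef(fit)
  if (anyNA(cf)) {            # degenerate design: single regime observed
    sl <- coef(lm(y ~ t))
    cf <- c(sl[1], sl[2], sl[2])
  }
  tend <- days_to_months(treatment_end(schedule))
  intr <- t <= tend + 1e-9
  alpha <- if (sum(intr) >= 2) unname(coef(lm(y[intr] ~ t[intr]))[2])
           else unname(coef(lm(y ~ t))[2])
  post <- y[t > tend + 1e-9]
  n <- if (length(post)) min(post) else min(y)
  c(alpha = alpha, n = n, y0 = unname(cf[1]), a = unname(cf[2]),
    b = unname(cf[3]))
}

#' CML time-course features
#'
#' The bi-exponential remission course is summarized by its two-straight-line
#' approximation on the log10 scale: a continuous two-segment fit with the
#' breakpoint chosen by exhaustive search over interior measurement times
#' (minimal SSE, earliest time on ties). Features: `A`, `alpha` (intercept
#' and slope of the first segment), `B`, `beta` (intercept at `t = 0` and
#' slope of the second segment), `sigma` (RMSE of the two-segment fit),
#' `t_stop`, and `last_value` (last measured log10 burden before cessation,
#' or before the half-dose year for AS). For the AS variant the response to
#' dose reduction is added: `gamma` and `C` (slope and intercept of a line
#' over the half-dose window, intercept taken at the start of that window),
#' `sigma_half` (RMSE of that line) and `last_pre_stop` (last measured
#' log10 value before cessation).
#'
#' @param input trajectory rows inside the input window.
#' @param schedule the patient's CML schedule.
#' @param variant variant tag; `"AS"` activates the half-dose features.
#' @return named numeric feature vector (7 entries, 11 for AS).
#' @export
cml_features <- function(input, schedule, variant = input$variant[1]) {
  ts <- schedule$t_stop
  pre_end <- if (variant == "AS") ts - 12 else ts
  pre <- input[input$time_months < pre_end - 1e-9 |
                 (variant != "AS" & input$time_months <= pre_end + 1e-9), ,
               drop = FALSE]
  if (all(pre$censored)) stop("all pre-cessation points censored")
  if (nrow(pre) < 4) stop("insufficient data for two-segment fit")
  t <- pre$time_months
  y <- log10(pre$burden_pct)
  seg <- fit_two_segments(t, y)
  if (seg$alpha > 1e-9 || seg$beta > 1e-9)
    warning("non-decreasing remission segment (slope > 0)")
  out <- c(A = seg$A, alpha = seg$alpha, B = seg$B, beta = seg$beta,
           sigma = seg$sigma, t_stop = ts, last_value = y[length(y)])
  if (variant == "AS") {
    half <- input[input$time_months >= ts - 12 - 1e-9, , drop = FALSE]
    if (nrow(half) < 2) stop("insufficient points in the half-dose window")
    th <- half$time_months - (ts - 12)
    yh <- log10(half$burden_pct)
    hf <- coef(lm(yh ~ th))
    res <- yh - (hf[1] + hf[2] * th)
    out <- c(out, gamma = unname(hf[2]), C = unname(hf[1]),
             sigma_half = sqrt(mean(res^2)),
             last_pre_stop = yh[length(yh)])
  }
  out
}

# continuous two-segment least squares; breakpoint by exhaustive search over
# interior observation times
fit_two_segments <- function(t, y) {
  stopifnot(length(t) >= 4)
  cands <- t[2:(length(t) - 1)]
  best <- NULL
  for (bp in cands) {
    h <- pmax(0, t - bp)
    fit <- lm(y ~ t + h)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      cf <- coef(fit)
      if (anyNA(cf)) next
      best <- list(sse = sse, bp = bp, cf = cf)
    }
  }
  if (is.null(best)) {  # collinear fallback: single line
    cf <- coef(lm(y ~ t))
    best <- list(sse = sum(lm(y ~ t)$residuals^2), bp = t[2],
                 cf = c(cf, 0))
  }
  A <- unname(best$cf[1])
  alpha <- unname(best$cf[2])
  beta <- alpha + unname(best$cf[3])
  # intercept of the second segment extrapolated to t = 0
  B <- A + best$bp * (alpha - beta)
  list(A = A, alpha = alpha, B = B, beta = beta, breakpoint = best$bp,
       sigma = sqrt(best$sse / length(t)))
}

#' Feature matrix for a cohort variant
#'
#' Extracts the disease-specific features from every patient's input window
#' and binds them with the ground-truth label. Patients whose series cannot
#' be featurized (too few points, fully censored) are dropped with a
#' warning; more than 5 percent failures abort.
#'
#' @param cohort a [generate_cohort()] result.
#' @param trajs variant trajectories from [degrade_cohort()].
#' @param variant variant tag of `trajs`.
#' @return data frame: `patient_id`, `label`, then one column per feature
#'   (5 for AML; 7 for CML, 11 for CML AS), in fixed order.
#' @export
feature_matrix <- function(cohort, trajs, variant) {
  recs <- cohort$records
  stopifnot(length(recs) == length(trajs))
  rows <- vector("list", length(recs))
  failed <- character(0)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    fv <- tryCatch({
      inp <- split_windows(trajs[[i]], rec$disease, rec$schedule)$input
      if (rec$disease == "AML") aml_features(inp, rec$schedule)
      else cml_features(inp, rec$schedule, variant)
    }, error = function(e) NULL)
    if (is.null(fv)) failed <- c(failed, rec$id)
    else rows[[i]] <- data.frame(patient_id = rec$id, label = rec$relapse,
                                 t(fv))
  }
  if (length(failed) > 0.05 * length(recs))
    stop("featurization failed for ", length(failed), " of ", length(recs),
         " patients; generator and feature settings are inconsistent")
  if (length(failed))
    warning("dropped ", length(failed), " unfeaturizable patient(s): ",
            paste(head(failed, 5), collapse = ", "))
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
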