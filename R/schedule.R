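# Treatment schedules. AML: a list of non-overlapping chemotherapy cycles
# given in days since treatment start. CML: continuous TKI dosing from t = 0,
# optionally halved over the last 12 months before cessation, then stopped.

#' AML chemotherapy schedule
#'
#' @param cycles two-column matrix (or data.frame) of cycle start and end
#'   days; cycles must be time-ordered and non-overlapping.
#' @return object of class `treatment_schedule`.
#' @export
aml_schedule <- function(cycles) {
  cycles <- as.matrix(cycles)
  if (ncol(cycles) != 2) stop("cycles must have two columns (start, end)")
  colnames(cycles) <- c("start", "end")
  if (any(cycles[, 2] <= cycles[, 1])) stop("cycle end must exceed cycle start")
  if (nrow(cycles) > 1) {
    if (is.unsorted(cycles[, 1], strictly = TRUE)) stop("cycles must be time-ordered")
    if (any(cycles[-1, 1] <= cycles[-nrow(cycles), 2]))
      stop("cycles must not overlap")
  }
  structure(list(disease = "AML", cycles = cycles), class = "treatment_schedule")
}

#' CML dosing schedule
#'
#' Full TKI dose on `[0, t_stop)` (months), optionally reduced to half dose
#' on `[half_dose_start, t_stop)`, zero dose afterwards.
#'
#' @param t_stop therapy cessation time in months (> 0).
#' @param half_dose_start optional start of the half-dose interval; the
#'   interval always ends exactly at `t_stop`.
#' @return object of class `treatment_schedule`.
#' @export
cml_schedule <- function(t_stop, half_dose_start = NULL) {
  if (!is.numeric(t_stop) || t_stop <= 0) stop("t_stop must be > 0")
  if (!is.null(half_dose_start)) {
    if (half_dose_start <= 0 || half_dose_start >= t_stop)
      stop("half-dose interval must lie strictly inside (0, t_stop)")
  }
  structure(list(disease = "CML", t_stop = t_stop,
                 half_dose_start = half_dose_start),
            class = "treatment_schedule")
}

# piecewise-constant dose: breakpoints (model time units) and values,
# value[i] applies on [t[i], t[i+1]), last value extends to +Inf
dose_segments <- function(schedule) {
  if (schedule$disease == "AML") {
    cy <- schedule$cycles
    if (nrow(cy) == 0) return(list(t = 0, v = 0))
    t <- c(0)
    v <- c()
    for (i in seq_len(nrow(cy))) {
      if (cy[i, 1] > t[length(t)]) {
        v <- c(v, 0)
        t <- c(t, cy[i, 1])
      }
      v <- c(v, 1)
      t <- c(t, cy[i, 2])
    }
    v <- c(v, 0)
    list(t = t, v = v)
  } else {
    if (is.null(schedule$half_dose_start)) {
      list(t = c(0, schedule$t_stop), v = c(1, 0))
    } else {
      list(t = c(0, schedule$half_dose_start, schedule$t_stop),
           v = c(1, 0.5, 0))
    }
  }
}

# dose value at time t (model units)
dose_at <- function(schedule, t) {
  seg <- dose_segments(schedule)
  idx <- findInterval(t, seg$t)
  idx[idx < 1] <- 1
  seg$v[idx]
}

treatment_end <- function(schedule) {
  if (schedule$disease != "AML") stop("treatment_end is defined for AML schedules")
  max(schedule$cycles[, 2])
}

#' Sample a clinical treatment schedule
#'
#' AML: 3 to 5 chemotherapy cycles of one week (days `[start, start + 6]`),
#' the first starting at day 0, subsequent starts spaced 33 to 38 days apart
#' (uniform integers), emulating induction/consolidation blocks; treatment
#' always ends before month 6. CML: continuous full dose until a cessation
#' time drawn from the truncated-normal cessation sampler (the half-dose
#' interval is added only by the AS transform).
#'
#' @param disease `"AML"` or `"CML"`.
#' @param n number of schedules to draw.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param cessation settings list for the CML cessation sampler
#'   (see [sample_cessation()]).
#' @return a `treatment_schedule` for `n = 1`, else a list of them.
#' @export
sample_schedule <- function(disease = c("AML", "CML"), n = 1, seed = NULL,
                            cessation = list()) {
  disease <- match.arg(disease)
  out <- with_seed(seed, {
    if (disease == "AML") {
      lapply(seq_len(n), function(i) {
        k <- sample(3:5, 1)
        gaps <- sample(33:38, k - 1, replace = TRUE)
        starts <- cumsum(c(0, gaps))
        aml_schedule(cbind(starts, starts + 6))
      })
    } else {
      ts <- do.call(sample_cessation, c(list(n = n), cessation))
      lapply(ts, cml_schedule)
    }
  })
  if (n == 1) out[[1]] else out
}
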