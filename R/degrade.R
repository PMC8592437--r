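# Data-quality ladder: D (dense, exact) -> DN (+ log-normal noise) ->
# SN (+ clinical sparsity) -> AP (+ detection limit) and the refined
# schemes AS (AML: informative measurement times; CML: half-dose year
# before cessation). Ground-truth labels always come from D.

#' Degradation configuration
#'
#' @param noise_sd measurement noise SD on the log10 scale, per disease
#'   (dex). Defaults: AML 0.3, CML 0.35.
#' @param lod detection limit in percent (values below are censored at the
#'   limit). Default 0.01 for both diseases.
#' @param count_dist per-patient measurement-count distribution inside the
#'   input window, per disease: list with `values` and `probs`. Defaults
#'   reproduce the clinical medians (AML 4, CML 25).
#' @param aml_as_at_cycle_start if `TRUE`, the AML refined scheme measures on
#'   the first day of each chemotherapy cycle instead of the last.
#' @param seed seed for the stochastic transforms.
#' @return object of class `degrade_config`.
#' @export
degrade_config <- function(noise_sd = c(AML = 0.3, CML = 0.35),
                           lod = c(AML = 0.01, CML = 0.01),
                           count_dist = NULL,
                           aml_as_at_cycle_start = FALSE,
                           seed = 1) {
  count_dist <- count_dist %||% list(
    # clinical counts skew low for AML: median 4 over a 3..6 range
    AML = list(values = 3:6, probs = c(0.25, 0.35, 0.25, 0.15)),
    CML = list(values = 15:35, probs = rep(1 / 21, 21))
  )
  for (d in c("AML", "CML")) {
    cd <- count_dist[[d]]
    if (any(cd$values < 2)) stop("sparsity counts must be >= 2")
    if (abs(sum(cd$probs) - 1) > 1e-8) stop("count probabilities must sum to 1")
  }
  if (any(noise_sd < 0)) stop("noise SD must be >= 0")
  if (any(lod <= 0)) stop("detection limit must be > 0")
  structure(list(noise_sd = noise_sd, lod = lod, count_dist = count_dist,
                 aml_as_at_cycle_start = aml_as_at_cycle_start,
                 seed = as.integer(seed)),
            class = "degrade_config")
}

#' Add multiplicative measurement noise (D to DN)
#'
#' Each measured value is replaced by
#' `10^(log10(value) + N(0, sd^2))` with independent draws; times are
#' unchanged.
#'
#' @param traj a variant-D trajectory.
#' @param sd noise SD on the log10 scale (dex).
#' @param seed optional seed.
#' @return trajectory with variant `"DN"`.
#' @export
add_noise <- function(traj, sd, seed = NULL) {
  if (sd < 0) stop("noise SD must be >= 0")
  if (!identical(traj$variant[1], "D"))
    stop("add_noise expects a dense noise-free (D) trajectory")
  out <- traj
  if (sd > 0)
    out$burden_pct <- with_seed(seed,
      10^(log10(traj$burden_pct) + rnorm(nrow(traj), 0, sd)))
  out$variant <- "DN"
  out
}

#' Thin a trajectory to clinical measurement frequency (DN to SN)
#'
#' Draws a per-patient measurement count from `count_dist`, always retains
#' the first and the last point of the input window, samples the remaining
#' in-window points uniformly without replacement, and thins post-window
#' points to a matching sparse grid (evenly spaced indices) so the label
#' horizon keeps a realistic density.
#'
#' @param traj a DN trajectory.
#' @param disease disease tag (sets the input window).
#' @param schedule the patient's schedule (CML window end is `t_stop`).
#' @param count_dist list with `values` and `probs`.
#' @param seed optional seed.
#' @return trajectory with variant `"SN"`.
#' @export
sparsify <- function(traj, disease, schedule, count_dist, seed = NULL) {
  wend <- input_window_end(disease, schedule)
  win <- which(traj$time_months <= wend + 1e-9)
  post <- which(traj$time_months > wend + 1e-9)
  if (length(win) < 2) stop("input window has fewer than 2 points")
  with_seed(seed, {
    k <- count_dist$values[sample.int(length(count_dist$values), 1,
                                      prob = count_dist$probs)]
    if (k >= length(win)) {
      warning("requested ", k, " points but only ", length(win),
              " available; keeping all")
      keep <- win
    } else {
      interior <- win[-c(1, length(win))]
      keep <- sort(c(win[1], win[length(win)],
                     if (k > 2) sample(interior, k - 2)))
    }
    keep_post <- if (length(post)) {
      ratio <- length(keep) / length(win)
      npost <- max(1L, ceiling(length(post) * ratio))
      post[unique(round(seq(1, length(post), length.out = npost)))]
    } else integer(0)
    out <- traj[c(keep, keep_post), , drop = FALSE]
    rownames(out) <- NULL
    out$variant <- "SN"
    out
  })
}

#' Censor values below the detection limit (SN to AP)
#'
#' @param traj trajectory.
#' @param lod detection limit in percent.
#' @return trajectory with variant `"AP"`; values below `lod` replaced by
#'   `lod` with `censored = TRUE`.
#' @export
apply_detection_limit <- function(traj, lod) {
  if (lod <= 0) stop("detection limit must be > 0")
  out <- traj
  cens <- out$burden_pct < lod
  out$burden_pct[cens] <- lod
  out$censored <- out$censored | cens
  out$variant <- "AP"
  out
}

#' Refined measurement / dosing scheme (AS)
#'
#' AML: measurements at the end of each chemotherapy cycle (optionally the
#' first day, see [degrade_config()]) plus one every six weeks from
#' treatment end until month 9; values are read from the noise-free model
#' course at those exact times, then noise and the detection limit are
#' applied as for AP. CML: the course is re-simulated with half dose over
#' the final 12 months before cessation; measurements are the patient's AP
#' times before the half-dose year plus monthly points during it, again with
#' noise and detection limit.
#'
#' @param patient a patient record from [generate_cohort()].
#' @param cfg a [degrade_config()].
#' @param ap_traj the patient's AP trajectory (required for CML so the
#'   pre-perturbation sampling matches AP exactly; ignored for AML).
#' @param seed optional seed.
#' @return trajectory with variant `"AS"`.
#' @export
as_scheme <- function(patient, cfg, ap_traj = NULL, seed = NULL) {
  disease <- patient$disease
  sdlog <- cfg$noise_sd[[disease]]
  lod <- cfg$lod[[disease]]
  if (disease == "AML") {
    cy <- patient$schedule$cycles
    anchor <- if (isTRUE(cfg$aml_as_at_cycle_start)) cy[, 1] else cy[, 2]
    tend <- treatment_end(patient$schedule)
    extra <- seq(tend + 42, months_to_days(AML_WINDOW_MONTHS), by = 42)
    tt <- days_to_months(sort(unique(c(anchor, extra))))
    tt <- tt[tt > 0 & tt <= AML_WINDOW_MONTHS + 1e-9]
    dense <- simulate_course(patient$params, patient$schedule, tt,
                             patient_id = patient$id)
  } else {
    ts <- patient$schedule$t_stop
    if (ts < 12) stop("half-dose window undefined: cessation before month 12")
    if (is.null(ap_traj)) stop("CML AS requires the patient's AP trajectory")
    sched_half <- cml_schedule(ts, half_dose_start = ts - 12)
    pre <- ap_traj$time_months[ap_traj$time_months < ts - 12 - 1e-9]
    during <- seq(ts - 12, ts, by = 1)
    tt <- sort(unique(c(pre, during)))
    dense <- simulate_course(patient$params, sched_half, tt,
                             patient_id = patient$id)
  }
  noisy <- with_seed(seed,
    10^(log10(dense$burden_pct) + rnorm(nrow(dense), 0, sdlog)))
  out <- dense
  out$burden_pct <- noisy
  out$variant <- "D"   # transient tag; relabeled below
  out <- apply_detection_limit(out, lod)
  out$variant <- "AS"
  out
}

#' Split a trajectory into prediction input and label horizon
#'
#' AML: input window is everything up to month 9, the horizon the following
#' 15 months. CML: input up to therapy cessation, horizon the following ten
#' years.
#'
#' @param traj trajectory.
#' @param disease disease tag.
#' @param schedule patient schedule.
#' @return list with `input` (trajectory rows inside the window) and
#'   `horizon` (numeric `c(start, end)` in months).
#' @export
split_windows <- function(traj, disease, schedule) {
  wend <- input_window_end(disease, schedule)
  input <- traj[traj$time_months <= wend + 1e-9, , drop = FALSE]
  if (!nrow(input)) stop("empty input window")
  rownames(input) <- NULL
  hor <- if (disease == "AML") c(AML_WINDOW_MONTHS, AML_HORIZON_MONTHS)
         else c(schedule$t_stop, schedule$t_stop + CML_POST_STOP_MONTHS)
  list(input = input, horizon = hor)
}

#' Materialize a data-quality variant for a whole cohort
#'
#' Applies the ladder D -> DN -> SN -> AP (and AS) per patient with seeds
#' derived from the configuration seed and the patient id, so every variant
#' of a patient shares the same noise realization where the ladder overlaps.
#'
#' @param cohort a [generate_cohort()] result.
#' @param variant one of `"D"`, `"DN"`, `"SN"`, `"AP"`, `"AS"`.
#' @param cfg a [degrade_config()].
#' @return list of trajectories, one per patient, in cohort order.
#' @export
degrade_cohort <- function(cohort, variant = c("D", "DN", "SN", "AP", "AS"),
                           cfg = degrade_config()) {
  variant <- match.arg(variant)
  lapply(cohort$records, function(rec) degrade_patient(rec, variant, cfg))
}

degrade_patient <- function(rec, variant, cfg) {
  disease <- rec$disease
  if (variant == "D") return(rec$dense)
  dn <- add_noise(rec$dense, cfg$noise_sd[[disease]],
                  seed = derive_seed(cfg$seed, paste0("noise:", rec$id)))
  if (variant == "DN") return(dn)
  sn <- sparsify(dn, disease, rec$schedule, cfg$count_dist[[disease]],
                 seed = derive_seed(cfg$seed, paste0("sparse:", rec$id)))
  if (variant == "SN") return(sn)
  ap <- apply_detection_limit(sn, cfg$lod[[disease]])
  if (variant == "AP") return(ap)
  as_scheme(rec, cfg, ap_traj = ap,
            seed = derive_seed(cfg$seed, paste0("as:", rec$id)))
}
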