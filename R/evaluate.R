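# Cross-validated benchmark over the disease x variant x method grid.

#' Stratified k-fold partition
#'
#' Partitions `1:n` into `k` disjoint test sets whose sizes differ by at
#' most one, stratified by label (class proportions per fold within one
#' patient of the global proportion). A class with fewer than `k` members
#' triggers an unstratified fallback with a warning.
#'
#' @param n number of units.
#' @param k number of folds.
#' @param seed optional seed.
#' @param labels optional stratification labels (length `n`).
#' @return list of `k` integer vectors (test indices).
#' @export
kfold_split <- function(n, k = 10, seed = NULL, labels = NULL) {
  if (n < k) stop("need at least k units for k folds")
  with_seed(seed, {
    if (!is.null(labels)) {
      labels <- as.character(labels)
      if (min(table(labels)) < k) {
        warning("a class has fewer than k members; folds are unstratified")
        labels <- NULL
      }
    }
    ordered <- if (is.null(labels)) {
      sample(n)
    } else {
      unlist(lapply(unique(labels), function(l) sample(which(labels == l))),
             use.names = FALSE)
    }
    folds <- rep(list(integer(0)), k)
    for (pos in seq_along(ordered)) {
      f <- ((pos - 1) %% k) + 1
      folds[[f]] <- c(folds[[f]], ordered[pos])
    }
    lapply(folds, sort)
  })
}

#' Prediction accuracy from confusion counts
#'
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param tp,tn,fp,fn confusion counts (all >= 0, total > 0).
#' @return fraction of correct predictions.
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0")
  total <- sum(counts)
  if (total == 0) stop("accuracy undefined for zero predictions")
  (tp + tn) / total
}

#' Evaluation configuration
#'
#' @param k number of cross-validation folds.
#' @param seed master seed (folds, inner splits, per-patient fit seeds,
#'   network training).
#' @param degrade a [degrade_config()].
#' @param nn an [nn_config()].
#' @param mm list of [fit_mechanistic()] settings (`restarts`, `control`).
#' @param inner_val fraction of the training fold carved out (stratified)
#'   as the network's validation set for restart selection/early stopping.
#' @return object of class `eval_config`.
#' @export
eval_config <- function(k = 10, seed = 1, degrade = degrade_config(),
                        nn = nn_config(), mm = list(restarts = 5),
                        inner_val = 0.1) {
  structure(list(k = k, seed = as.integer(seed), degrade = degrade, nn = nn,
                 mm = mm, inner_val = inner_val),
            class = "eval_config")
}

#' Run the cross-validated prediction benchmark
#'
#' For every requested data-quality variant, materializes the degraded
#' trajectories, then evaluates every requested method on identical
#' stratified test folds: GLM and NN are trained on the remaining folds (the
#' NN additionally carves a stratified inner validation split out of its
#' training data), while the mechanistic model needs no training and is fit
#' patient-by-patient on the degraded input window of the same variant.
#'
#' @param cohort a labeled [generate_cohort()] cohort.
#' @param variants subset of `c("D","DN","SN","AP","AS")`.
#' @param methods subset of `c("MM","GLM","NN")`.
#' @param cfg an [eval_config()].
#' @return object of class `eval_report`: `tidy` (per-fold rows with
#'   accuracies and confusion counts), `summary` (mean and SD across folds),
#'   `predictions`, and `meta`.
#' @export
run_experiment <- function(cohort, variants = c("D", "DN", "SN", "AP"),
                           methods = c("MM", "GLM", "NN"),
                           cfg = eval_config()) {
  disease <- cohort$config$disease
  recs <- cohort$records
  n <- length(recs)
  y <- cohort_labels(cohort)
  ids <- vapply(recs, function(r) r$id, "")
  schedules <- lapply(recs, function(r) r$schedule)
  folds <- kfold_split(n, cfg$k, seed = derive_seed(cfg$seed, "folds"),
                       labels = y)
  tidy <- list()
  preds <- list()
  for (v in variants) {
    trajs <- degrade_cohort(cohort, v, cfg$degrade)
    inputs <- lapply(seq_len(n), function(i)
      split_windows(trajs[[i]], disease, schedules[[i]])$input)
    score <- matrix(NA_real_, n, length(methods),
                    dimnames = list(NULL, methods))
    if ("MM" %in% methods) {
      for (i in seq_len(n)) {
        pm <- tryCatch(
          predict_mm(inputs[[i]], disease, schedules[[i]],
                     cohort$config$prior,
                     seed = derive_seed(cfg$seed, paste0("mm:", v, ids[i])),
                     restarts = cfg$mm$restarts %||% 5,
                     lod = cfg$degrade$lod[[disease]],
                     control = cfg$mm$control %||% list()),
          error = function(e) NULL)
        score[i, "MM"] <- if (is.null(pm)) NA_real_ else pm$score
      }
    }
    fm <- NULL
    if ("GLM" %in% methods) {
      fm <- suppressWarnings(feature_matrix(cohort, trajs, v))
      frow <- match(ids, fm$patient_id)
    }
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(n), test)
      if ("GLM" %in% methods) {
        tr <- frow[train]
        te <- frow[test]
        clf <- train_glm(fm[tr[!is.na(tr)], -(1:2), drop = FALSE],
                         fm$label[tr[!is.na(tr)]])
        ok <- !is.na(te)
        pg <- predict_glm(clf, fm[te[ok], -(1:2), drop = FALSE])
        score[test[ok], "GLM"] <- pg$score
      }
      if ("NN" %in% methods) {
        val <- stratified_subsample(train, y[train], cfg$inner_val,
                                    seed = derive_seed(cfg$seed,
                                                       paste0("val:", v, f)))
        core <- setdiff(train, val)
        enc_tr <- encode_sequences(inputs[core], schedules[core])
        enc_va <- encode_sequences(inputs[val], schedules[val],
                                   scale = enc_tr$scale)
        enc_te <- encode_sequences(inputs[test], schedules[test],
                                   scale = enc_tr$scale)
        nncfg <- cfg$nn
        nncfg$seed <- derive_seed(cfg$seed, paste0("nn:", v, f))
        model <- train_nn(enc_tr, y[core], enc_va, y[val], nncfg)
        score[test, "NN"] <- predict_nn(model, enc_te)$score
      }
      for (m in methods) {
        sc <- score[test, m]
        miss <- sum(is.na(sc))
        if (miss > 0.05 * length(test))
          stop(sprintf("%s failed on %d of %d test patients (variant %s)",
                       m, miss, length(test), v))
        pred <- sc[!is.na(sc)] >= 0.5
        truth <- y[test][!is.na(sc)]
        tp <- sum(pred & truth); tn <- sum(!pred & !truth)
        fp <- sum(pred & !truth); fn <- sum(!pred & truth)
        tidy[[length(tidy) + 1]] <- data.frame(
          disease = disease, variant = v, method = m, fold = f,
          accuracy = accuracy(tp, tn, fp, fn),
          tp = tp, tn = tn, fp = fp, fn = fn, n_test = length(test))
      }
    }
    preds[[v]] <- data.frame(patient_id = ids, variant = v, label = y, score)
  }
  tidy <- do.call(rbind, tidy)
  summ <- aggregate(accuracy ~ disease + variant + method, tidy,
                    function(a) c(mean = mean(a), sd = sd(a)))
  summ <- data.frame(summ[1:3], mean = summ$accuracy[, "mean"],
                     sd = summ$accuracy[, "sd"])
  structure(list(tidy = tidy, summary = summ,
                 predictions = do.call(rbind, preds),
                 meta = list(n = n, k = cfg$k, seed = cfg$seed,
                             variants = variants, methods = methods,
                             relapse_fraction = mean(y))),
            class = "eval_report")
}

# stratified subsample of about frac of idx (at least 1 per class)
stratified_subsample <- function(idx, labels, frac, seed = NULL) {
  with_seed(seed, {
    take <- unlist(lapply(unique(as.character(labels)), function(l) {
      cand <- idx[labels == l]
      sample(cand, max(1, round(frac * length(cand))))
    }), use.names = FALSE)
    sort(take)
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$meta$n, "patients,", x$meta$k, "folds\n")
  s <- x$summary
  s$mean <- round(s$mean, 3)
  s$sd <- round(s$sd, 3)
  print(s, row.names = FALSE)
  invisible(x)
}
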