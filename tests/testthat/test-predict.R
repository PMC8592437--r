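# The three predictors: mechanistic refitting, ridge-IRLS logistic
# regression, bidirectional LSTM.

test_that("the fitting objective vanishes at the generating parameters", {
  co <- fixture_cohort("AML", 4)
  r <- co$records[[1]]
  inp <- split_windows(r$dense, "AML", r$schedule)$input
  obs <- relapsim:::mm_observations(inp)
  fn <- relapsim:::mm_objective_fn(obs, "AML", r$schedule, r$params,
                                   c("p_L", "t_QA_L"), 0.01, rtol = 1e-8)
  truth <- log(c(r$params$p_L, r$params$t_QA_L))
  expect_lt(fn(truth), 1e-8)
  expect_gt(fn(truth + c(0.3, 0)), 1e-3)   # objective discriminates
})

test_that("censored points contribute one-sidedly", {
  co <- fixture_cohort("AML", 12)
  nadir <- vapply(co$records, function(r)
    min(split_windows(r$dense, "AML", r$schedule)$input$burden_pct), 0)
  r <- co$records[[which.min(nadir)]]
  inp <- split_windows(r$dense, "AML", r$schedule)$input
  # censor the deepest points at a limit strictly above the simulated values
  lod <- min(inp$burden_pct) * 10
  idx <- which(inp$burden_pct < lod)
  expect_gt(length(idx), 0)
  cens <- inp
  cens$burden_pct[idx] <- lod
  cens$censored[idx] <- TRUE
  obs <- relapsim:::mm_observations(cens)
  fn <- relapsim:::mm_objective_fn(obs, "AML", r$schedule, r$params,
                                   c("p_L", "t_QA_L"), lod, rtol = 1e-8)
  # simulated truth lies below the limit at every censored point: zero loss
  expect_lt(fn(log(c(r$params$p_L, r$params$t_QA_L))), 1e-8)
})

test_that("mechanistic prediction is self-consistent and deterministic", {
  co <- fixture_cohort("AML", 12)
  prior <- co$config$prior
  lab <- cohort_labels(co)
  pred <- vapply(co$records, function(r) {
    inp <- split_windows(r$dense, "AML", r$schedule)$input
    predict_mm(inp, "AML", r$schedule, prior,
               seed = derive_seed(3, r$id))$prediction
  }, TRUE)
  expect_gte(mean(pred == lab), 0.9)
  r <- co$records[[1]]
  inp <- split_windows(r$dense, "AML", r$schedule)$input
  f1 <- fit_mechanistic(inp, "AML", r$schedule, prior, seed = 11)
  f2 <- fit_mechanistic(inp, "AML", r$schedule, prior, seed = 11)
  expect_identical(f1$par, f2$par)
  expect_error(fit_mechanistic(inp[1, , drop = FALSE], "AML", r$schedule,
                               prior), "at least 2")
})

test_that("logistic regression separates toy data and matches an oracle", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 1, 1, 1)
  clf <- train_glm(x, y)
  pr <- predict_glm(clf, x)
  expect_equal(mean(pr$prediction == y), 1)
  expect_true(all(pr$score > 0 & pr$score < 1))

  # fixed 20-row dataset: IRLS coefficients vs direct optimization of the
  # ridge-penalized log-likelihood
  set.seed(99)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("u", "v")))
  yy <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(20, 0, 0.8) > 0)
  clf <- train_glm(X, yy, lambda = 1e-4)
  Xs <- scale(X)
  negll <- function(b) {
    eta <- b[1] + Xs %*% b[2:3]
    sum(log1p(exp(eta)) - yy * eta) + 0.5 * 1e-4 * sum(b[2:3]^2)
  }
  oracle <- optim(c(0, 0, 0), negll, method = "BFGS",
                  control = list(reltol = 1e-14))$par
  expect_equal(unname(clf$coef), oracle, tolerance = 1e-3)

  # constant columns are dropped with a warning
  X2 <- cbind(X, const = 1)
  expect_warning(clf2 <- train_glm(X2, yy), "constant")
  expect_equal(unname(clf2$coef), unname(clf$coef), tolerance = 1e-10)
  expect_error(train_glm(X, rep(1, 20)), "single class")
})

test_that("sequence encoding scales, pads and masks correctly", {
  co <- fixture_cohort("AML", 8)
  cfgd <- degrade_config(seed = 2)
  sn <- degrade_cohort(co, "SN", cfgd)
  inputs <- lapply(seq_along(sn), function(i)
    split_windows(sn[[i]], "AML", co$records[[i]]$schedule)$input)
  scheds <- lapply(co$records, function(r) r$schedule)
  enc <- encode_sequences(inputs, scheds)
  expect_identical(enc$lengths, vapply(inputs, nrow, 0L))
  # burden channel inside [-1, 1]; invertible with the stored scale
  for (i in seq_along(inputs)) {
    ch <- enc$sequences[[i]][, "burden"]
    expect_true(all(ch >= -1 - 1e-9 & ch <= 1 + 1e-9))
    back <- (ch + 1) / 2 * (enc$scale[2] - enc$scale[1]) + enc$scale[1]
    expect_equal(back, log10(inputs[[i]]$burden_pct), tolerance = 1e-9)
    expect_true(all(enc$sequences[[i]][, "time"] <= 1 + 1e-9))
  }
  pad <- pad_sequences(enc$sequences)
  expect_equal(rowSums(pad$mask), as.numeric(enc$lengths)) # mask sum = length
  # padding stays zero wherever the mask is off
  for (b in seq_along(inputs)) {
    off <- which(pad$mask[b, ] == 0)
    if (length(off)) expect_true(all(pad$tensor[b, off, ] == 0))
  }
  expect_error(encode_sequences(list(), scheds), "empty")
})

test_that("network gradients match finite differences", {
  set.seed(5)
  Xl <- lapply(c(4, 2, 6), function(n) matrix(rnorm(n * 3), n, 3))
  y <- c(1, 0, 1)
  w <- relapsim:::.nn_init_cpp(3L, 4L, c(3L))
  lg <- relapsim:::.nn_loss_grad_cpp(w, Xl, y)
  eps <- 1e-6
  worst <- 0
  for (nm in c("Wf", "Uf", "bf", "Wr", "Ur", "br")) {
    for (k in sample(length(w[[nm]]), min(8, length(w[[nm]])))) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
      num <- (relapsim:::.nn_loss_grad_cpp(wp, Xl, y)$loss -
                relapsim:::.nn_loss_grad_cpp(wm, Xl, y)$loss) / (2 * eps)
      worst <- max(worst, abs(num - lg$grad[[nm]][k]) /
                     max(1e-8, abs(num) + abs(lg$grad[[nm]][k])))
    }
  }
  for (li in 1:2) {
    for (k in sample(length(w$Wd[[li]]), min(6, length(w$Wd[[li]])))) {
      wp <- w; wp$Wd[[li]][k] <- wp$Wd[[li]][k] + eps
      wm <- w; wm$Wd[[li]][k] <- wm$Wd[[li]][k] - eps
      num <- (relapsim:::.nn_loss_grad_cpp(wp, Xl, y)$loss -
                relapsim:::.nn_loss_grad_cpp(wm, Xl, y)$loss) / (2 * eps)
      worst <- max(worst, abs(num - lg$grad$Wd[[li]][k]) /
                     max(1e-8, abs(num) + abs(lg$grad$Wd[[li]][k])))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the network learns a simple sequence rule and is reproducible", {
  set.seed(17)
  n <- 240
  seqs <- lapply(seq_len(n), function(i) {
    len <- sample(3:10, 1)
    matrix(rnorm(len * 3), len, 3)
  })
  y <- vapply(seqs, function(s) as.numeric(s[nrow(s), 2] > 0), 0)
  tr <- list(sequences = seqs[1:190], scale = c(-1, 1))
  va <- list(sequences = seqs[191:240], scale = c(-1, 1))
  cfg <- nn_config(hidden = 8, dense = 8, epochs = 150, patience = 30,
                   lr = 5e-3, restarts = 2, seed = 33)
  m <- train_nn(tr, y[1:190], va, y[191:240], cfg)
  expect_gte(m$val_acc, 0.95)
  pr <- predict_nn(m, va)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_gte(mean(pr$prediction == y[191:240]), 0.9)

  m2 <- train_nn(tr, y[1:190], va, y[191:240], cfg)
  expect_identical(m$run, m2$run)
  expect_identical(predict_nn(m2, va)$score, pr$score)

  # single-class validation set: selection falls back to loss, with warning
  expect_warning(
    train_nn(tr, y[1:190], list(sequences = seqs[191:195], scale = c(-1, 1)),
             rep(1, 5), nn_config(hidden = 4, epochs = 3, restarts = 2,
                                  seed = 1)),
    "single class")
})

test_that("the genetic algorithm refits the CML model on dense data", {
  cc <- fixture_cohort("CML", 8, seed = 301)
  prior <- cc$config$prior
  lab <- cohort_labels(cc)
  expect_true(any(lab) && any(!lab))
  pred <- vapply(cc$records, function(r) {
    inp <- split_windows(r$dense, "CML", r$schedule)$input
    predict_mm(inp, "CML", r$schedule, prior,
               seed = derive_seed(5, r$id),
               control = list(generations = 25))$prediction
  }, TRUE)
  expect_gte(mean(pred == lab), 0.75)
  r <- cc$records[[1]]
  inp <- split_windows(r$dense, "CML", r$schedule)$input
  expect_error(fit_mechanistic(inp[1:3, ], "CML", r$schedule, prior),
               "at least 4")
})
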