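# Sequence predictor: bidirectional LSTM over the raw input-window series.
# The network sees three channels per measurement: time scaled by the
# patient's window length, log10 burden scaled to [-1, 1] with training-fold
# statistics, and the censoring flag.

#' Neural network configuration
#'
#' @param hidden LSTM units per direction.
#' @param dense widths of the fully connected head (final binary output is
#'   added automatically).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation accuracy.
#' @param batch minibatch size.
#' @param lr learning rate (adaptive-moment optimizer).
#' @param restarts independently initialized training runs; the run with the
#'   highest validation accuracy is kept.
#' @param seed optional master seed for training.
#' @return object of class `nn_config`.
#' @export
nn_config <- function(hidden = 32, dense = 16, epochs = 100, patience = 10,
                      batch = 32, lr = 1e-3, restarts = 10, seed = NULL) {
  stopifnot(hidden >= 1, all(dense >= 1), restarts >= 1, batch >= 1,
            epochs >= 1)
  structure(list(hidden = as.integer(hidden), dense = as.integer(dense),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 batch = as.integer(batch), lr = lr,
                 restarts = as.integer(restarts), seed = seed),
            class = "nn_config")
}

#' Encode input windows as channel sequences
#'
#' @param inputs list of input-window trajectories.
#' @param schedules list of matching schedules (per-patient window length).
#' @param scale optional `c(min, max)` of log10 burden from the training
#'   fold; if `NULL`, computed from `inputs` and returned for reuse.
#' @return list: `sequences` (list of `T_i x 3` matrices), `lengths`,
#'   `scale`.
#' @export
encode_sequences <- function(inputs, schedules, scale = NULL) {
  if (!length(inputs)) stop("empty input list")
  disease <- inputs[[1]]$disease[1]
  logb <- lapply(inputs, function(tr) {
    if (!nrow(tr)) stop("empty series cannot be encoded")
    log10(tr$burden_pct)
  })
  if (is.null(scale)) {
    rng <- range(unlist(logb))
    if (diff(rng) < 1e-9) rng <- rng + c(-0.5, 0.5)
    scale <- rng
  }
  seqs <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    tr <- inputs[[i]]
    wlen <- input_window_end(disease, schedules[[i]])
    yb <- 2 * (logb[[i]] - scale[1]) / (scale[2] - scale[1]) - 1
    seqs[[i]] <- cbind(time = tr$time_months / wlen,
                       burden = yb,
                       censored = as.numeric(tr$censored))
  }
  list(sequences = seqs, lengths = vapply(seqs, nrow, 0L), scale = scale)
}

#' Pad encoded sequences into a tensor with a mask
#'
#' Front-aligned padding: real measurements occupy the leading time steps.
#'
#' @param sequences list of `T_i x D` matrices.
#' @return list: `tensor` (`B x T x D` array, zero padded) and `mask`
#'   (`B x T`, 1 for real points).
#' @export
pad_sequences <- function(sequences) {
  B <- length(sequences)
  Tm <- max(vapply(sequences, nrow, 0L))
  D <- ncol(sequences[[1]])
  tensor <- array(0, c(B, Tm, D))
  mask <- matrix(0, B, Tm)
  for (b in seq_len(B)) {
    n <- nrow(sequences[[b]])
    tensor[b, seq_len(n), ] <- sequences[[b]]
    mask[b, seq_len(n)] <- 1
  }
  list(tensor = tensor, mask = mask)
}

#' Train the bidirectional LSTM classifier
#'
#' Runs `cfg$restarts` independently initialized trainings and keeps the
#' network with the highest validation accuracy (ties: lower run index).
#' If the validation set contains a single class, selection falls back to
#' validation loss with a warning.
#'
#' @param train encoded training sequences (from [encode_sequences()]).
#' @param ytrain training labels.
#' @param val,yval validation sequences and labels (disjoint from training).
#' @param cfg an [nn_config()].
#' @return object of class `nn_classifier`.
#' @export
train_nn <- function(train, ytrain, val, yval, cfg = nn_config()) {
  X <- c(train$sequences, val$sequences)
  y <- c(as.numeric(ytrain), as.numeric(yval))
  tr_idx <- seq_along(train$sequences)
  va_idx <- length(train$sequences) + seq_along(val$sequences)
  one_class_val <- length(unique(y[va_idx])) < 2
  if (one_class_val)
    warning("validation set has a single class; selecting by validation loss")
  runs <- vector("list", cfg$restarts)
  for (r in seq_len(cfg$restarts)) {
    runs[[r]] <- with_seed(
      if (is.null(cfg$seed)) NULL else derive_seed(cfg$seed, paste0("run", r)),
      .nn_train_cpp(X, y, tr_idx, va_idx, cfg$hidden, cfg$dense, cfg$epochs,
                    cfg$batch, cfg$lr, cfg$patience))
  }
  crit <- if (one_class_val)
    -vapply(runs, function(r) r$val_loss, 0)
  else
    vapply(runs, function(r) r$val_acc, 0)
  best <- which.max(crit)  # which.max returns the first (lowest index) tie
  structure(list(weights = runs[[best]]$weights, run = best,
                 val_acc = runs[[best]]$val_acc,
                 val_loss = runs[[best]]$val_loss,
                 best_epoch = runs[[best]]$best_epoch,
                 scale = train$scale, cfg = cfg),
            class = "nn_classifier")
}

#' Predict with a trained LSTM classifier
#'
#' @param model [train_nn()] result.
#' @param encoded encoded sequences (use the training `scale`).
#' @return list: `score` (sigmoid probabilities) and `prediction`.
#' @export
predict_nn <- function(model, encoded) {
  p <- .nn_predict_cpp(model$weights, encoded$sequences)
  list(score = p, prediction = p >= 0.5)
}
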