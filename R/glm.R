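# Logistic-regression predictor on explicit features: ridge-stabilized
# iteratively reweighted least squares (IRLS). The small ridge penalty keeps
# the solution finite under complete separation, which happens routinely on
# the noise-free dense variant.

#' Train the logistic-regression classifier
#'
#' Features are z-scored with training statistics; constant columns are
#' dropped with a warning. The model is fit by IRLS on the penalized
#' log-likelihood with ridge penalty `lambda` on all coefficients except the
#' intercept.
#'
#' @param x numeric matrix or data frame of features (rows = patients).
#' @param y logical or 0/1 labels; both classes must be present.
#' @param lambda ridge penalty (default `1e-4`).
#' @param maxit,tol IRLS iteration controls.
#' @return object of class `glm_classifier`.
#' @export
train_glm <- function(x, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  keep <- apply(x, 2, function(col) sd(col) > 1e-12)
  if (!all(keep)) {
    warning("dropping constant feature column(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  xs <- scale(x, center = ctr, scale = scl)
  X <- cbind(1, xs)
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  structure(list(coef = drop(beta), center = ctr, scale = scl,
                 keep = keep, lambda = lambda, iterations = it),
            class = "glm_classifier")
}

#' Predict relapse probabilities from features
#'
#' @param clf a [train_glm()] classifier.
#' @param x feature matrix (same columns as training, before dropping).
#' @return list: `score` (probabilities in (0,1)) and `prediction`
#'   (`score >= 0.5`).
#' @export
predict_glm <- function(clf, x) {
  x <- as.matrix(x)[, clf$keep, drop = FALSE]
  xs <- scale(x, center = clf$center, scale = clf$scale)
  eta <- drop(cbind(1, xs) %*% clf$coef)
  p <- 1 / (1 + exp(-eta))
  list(score = p, prediction = p >= 0.5)
}
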