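#' Fit a PLS1 regression model by NIPALS
#'
#' Partial least squares regression of a single 0/1 class-membership
#' response on a spectral matrix — the engine behind both one-block and
#' (via the scaled super-matrix) multi-block PLS-DA. X and y are centered by
#' their training means; per component the weight is the covariance
#' direction `w_a = X'y / ||X'y||`, scores `t_a = X w_a`, x-loading
#' `p_a = X't_a / t_a't_a`, y-loading `q_a = y't_a / t_a't_a`, and X is
#' deflated by `t_a p_a'` (y deflation is redundant for a single response).
#' Regression coefficients are assembled through the standard identity
#' `b = W (P'W)^{-1} q`, accumulated so the coefficient vector of every
#' nested model with `1..A` components is available.
#'
#' If the deflated covariance `X'y` vanishes before `A` components are
#' extracted (X exhausted), extraction stops and the remaining nested
#' coefficient vectors repeat the last informative one; `n_lv_effective`
#' records how many components were actually extracted.
#'
#' @param X Numeric matrix, rows = samples, columns = channels.
#' @param y Numeric/integer 0/1 class vector (0 = normal, 1 = damaged);
#'   both classes must be present.
#' @param A Number of latent variables; at most `min(nrow(X) - 1, ncol(X))`.
#' @param row_keys Optional data frame identifying the training rows.
#' @return An object of class `pls_model` with elements `n_lv`,
#'   `n_lv_effective`, `x_mean`, `y_mean`, `W`, `T`, `P`, `q`, `b` (the
#'   coefficients at `A` components), `B` (channels x A matrix of nested
#'   coefficient vectors) and `row_keys`.
#' @export
fit_pls <- function(X, y, A, row_keys = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must contain only 0 and 1")
  if (length(unique(y)) < 2) stop("y is single-class; cannot fit PLS-DA")
  if (any(!is.finite(X))) stop("X contains non-finite values")
  if (A < 1 || A > min(n - 1, p))
    stop("A must lie in [1, min(samples - 1, channels)] = [1, ",
         min(n - 1, p), "]")
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  if (all(abs(Xc) < 1e-300)) stop("X has zero variance after centering")
  yc <- y - y_mean

  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  B <- matrix(0, p, A)
  R <- matrix(0, p, A)  # W (P'W)^{-1}, built incrementally
  b_cur <- numeric(p)
  eff <- 0L
  scale0 <- sqrt(sum(crossprod(Xc, yc)^2))
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(scale0, 1e-300)) {
      # X exhausted: remaining nested models equal the last informative one
      if (a > 1) B[, a:A] <- b_cur
      break
    }
    w <- w / nw
    tt <- Xc %*% w
    tsq <- sum(tt^2)
    pp <- crossprod(Xc, tt)[, 1] / tsq
    qq <- sum(yc * tt) / tsq
    Xc <- Xc - tt %*% t(pp)
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
    r <- w
    if (a > 1)
      for (j in seq_len(a - 1)) r <- r - sum(P[, j] * w) * R[, j]
    R[, a] <- r
    b_cur <- b_cur + r * qq
    B[, a] <- b_cur
    eff <- a
  }
  if (eff == 0L) stop("X has no covariance with y; nothing to extract")
  structure(
    list(n_lv = as.integer(A), n_lv_effective = eff,
         x_mean = x_mean, y_mean = y_mean,
         W = W[, seq_len(eff), drop = FALSE],
         T = Tm[, seq_len(eff), drop = FALSE],
         P = P[, seq_len(eff), drop = FALSE],
         q = q[seq_len(eff)],
         b = B[, A], B = B, row_keys = row_keys),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", length(x$x_mean), " channels, ", x$n_lv,
      " latent variable(s)", sep = "")
  if (x$n_lv_effective < x$n_lv)
    cat(" (", x$n_lv_effective, " effective)", sep = "")
  cat("\n")
  invisible(x)
}

#' Predict continuous class scores from a PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Matrix with the model's channel count.
#' @param n_lv Number of latent variables to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector `y_mean + (newdata - x_mean) b`.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " channels; model expects ",
         length(object$x_mean))
  if (n_lv < 1 || n_lv > object$n_lv) stop("n_lv out of range")
  b <- object$B[, n_lv]
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% b)
}

#' Threshold continuous scores into 0/1 class labels
#'
#' Standard PLS-DA cut on a 0/1 response: label 1 iff the score strictly
#' exceeds the threshold; a score equal to the threshold is assigned 0,
#' deterministically.
#'
#' @param scores Numeric vector of continuous predictions.
#' @param threshold Decision threshold (default 0.5, the midpoint of the
#'   class codes; no threshold tuning is performed).
#' @return Integer vector of 0/1 labels.
#' @export
classify <- function(scores, threshold = 0.5) {
  if (any(!is.finite(scores))) stop("non-finite scores")
  as.integer(scores > threshold)
}

#' Confusion statistics for a binary classification
#'
#' Sensitivity = fraction of damaged (class 1) called damaged; specificity =
#' fraction of healthy (class 0) called healthy; accuracy = fraction correct
#' overall. Raw fractions are retained; rounding to integer percentages
#' happens only in [report()] at the reporting boundary.
#'
#' @param pred,truth Equal-length 0/1 vectors; `truth` must contain both
#'   classes.
#' @return An object of class `confusion_stats`: counts `tp`, `fn`, `fp`,
#'   `tn`, `n1`, `n0` and fractions `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
confusion_stats <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth lengths differ (", length(pred), " vs ",
         length(truth), ")")
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L)) || length(unique(truth)) < 2)
    stop("truth must contain both classes 0 and 1")
  tp <- sum(pred == 1L & truth == 1L)
  fn <- sum(pred == 0L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  tn <- sum(pred == 0L & truth == 0L)
  n1 <- tp + fn; n0 <- tn + fp
  structure(
    list(tp = tp, fn = fn, fp = fp, tn = tn, n1 = n1, n0 = n0,
         sensitivity = tp / n1, specificity = tn / n0,
         accuracy = (tp + tn) / (n1 + n0)),
    class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf(
    "<confusion_stats> accuracy %.1f%% | sensitivity %.1f%% (n1 = %d) | specificity %.1f%% (n0 = %d)\n",
    100 * x$accuracy, 100 * x$sensitivity, x$n1, 100 * x$specificity, x$n0))
  invisible(x)
}
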