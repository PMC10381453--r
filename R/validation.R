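#' Leave-one-joint-out fold map
#'
#' One cross-validation fold per distinct joint: all samples of a joint —
#' damaged and their adjacent controls alike — leave the training set
#' together, so no within-animal information leaks between training and
#' test.
#'
#' @param design Study design table (see [validate_design()]).
#' @return Named list mapping joint id to its sample ids.
#' @export
logo_folds <- function(design) {
  design <- validate_design(design)
  joints <- unique(design$joint_id)
  if (length(joints) < 2)
    stop("leave-one-joint-out CV needs at least 2 joints")
  folds <- lapply(joints, function(j)
    design$sample_id[design$joint_id == j])
  names(folds) <- joints
  folds
}

#' Run leave-one-joint-out cross-validation
#'
#' For every fold, the held-out joint's samples are removed; the Frobenius
#' norm of each block and the centering means are recomputed from the
#' training rows only (no quantity derived from test rows enters the fit);
#' one model with `A_max` latent variables is fitted and the out-of-fold
#' continuous scores of every nested model with `1..A_max` components are
#' extracted. Misclassification and RMSE curves over the LV count, the
#' selected LV count (see [select_lv()]) and the confusion statistics at
#' the selected count are derived from the assembled out-of-fold scores.
#'
#' @param blocks A `block_set` or named list of preprocessed sample-level
#'   `spectral_block`s (one row per sample; see [average_replicates()]).
#' @param y 0/1 class vector aligned with the block rows.
#' @param design Study design covering every block row.
#' @param A_max Largest LV count to evaluate.
#' @param select_metric Prediction error minimised by the LV selection:
#'   `"misclass"` (default; the models are reported via classification
#'   metrics) or `"rmse"` of the continuous scores.
#' @param threshold Classification threshold passed to [classify()].
#' @return An object of class `cv_result`: `folds`, `scores` (samples x
#'   A_max out-of-fold continuous scores), `y`, `sample_id`, `misclass` and
#'   `rmse` curves, `chosen_a`, `stats` (confusion at `chosen_a`),
#'   `fold_norms` and `fold_means` (training-derived per fold).
#' @export
run_cv <- function(blocks, y, design, A_max = 10L,
                   select_metric = c("misclass", "rmse"), threshold = 0.5) {
  select_metric <- match.arg(select_metric)
  bs <- block_set(blocks)
  design <- validate_design(design)
  y <- as.numeric(y)
  keys <- bs$blocks[[1]]$row_keys
  n <- nrow(keys)
  if (length(y) != n) stop("y must have one entry per block row")
  if (A_max < 1) stop("A_max must be >= 1")
  if (!all(keys$sample_id %in% design$sample_id))
    stop("block rows contain sample ids absent from the design")
  folds <- logo_folds(design[design$sample_id %in% keys$sample_id, ])

  mats <- lapply(bs$blocks, function(b) b$intensities)
  scores <- matrix(NA_real_, n, A_max)
  fold_norms <- list(); fold_means <- list()
  for (j in names(folds)) {
    test <- keys$sample_id %in% folds[[j]]
    train <- !test
    if (length(unique(y[train])) < 2)
      stop("training set of fold '", j, "' is single-class")
    norms <- vapply(seq_along(mats), function(k)
      sqrt(sum(mats[[k]][train, ]^2)), numeric(1))
    names(norms) <- names(bs$blocks)
    if (any(norms == 0))
      stop("zero training Frobenius norm in fold '", j, "'")
    Xtr <- do.call(cbind, mapply(function(M, nm) M[train, , drop = FALSE] / nm,
                                 mats, norms, SIMPLIFY = FALSE))
    Xte <- do.call(cbind, mapply(function(M, nm) M[test, , drop = FALSE] / nm,
                                 mats, norms, SIMPLIFY = FALSE))
    A_fit <- min(A_max, sum(train) - 1L, ncol(Xtr))
    fit <- fit_pls(Xtr, y[train], A_fit)
    for (a in seq_len(A_max))
      scores[test, a] <- predict(fit, Xte, n_lv = min(a, A_fit))
    fold_norms[[j]] <- norms
    fold_means[[j]] <- fit$x_mean
  }
  misclass <- vapply(seq_len(A_max), function(a)
    mean(classify(scores[, a], threshold) != y), numeric(1))
  rmse <- vapply(seq_len(A_max), function(a)
    sqrt(mean((scores[, a] - y)^2)), numeric(1))
  cv <- structure(
    list(folds = folds, scores = scores, y = y, sample_id = keys$sample_id,
         A_max = as.integer(A_max), misclass = misclass, rmse = rmse,
         select_metric = select_metric, threshold = threshold,
         fold_norms = fold_norms, fold_means = fold_means),
    class = "cv_result")
  cv$chosen_a <- select_lv(cv)
  cv$stats <- confusion_stats(classify(scores[, cv$chosen_a], threshold), y)
  cv
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", length(x$folds), " folds, LV* = ", x$chosen_a,
      ", out-of-fold accuracy ", sprintf("%.1f%%", 100 * x$stats$accuracy),
      "\n", sep = "")
  invisible(x)
}

#' Select the latent-variable count minimising cross-validation error
#'
#' Arg-min of the out-of-fold prediction error over the LV count
#' (misclassification rate by default, RMSE if the CV was run with
#' `select_metric = "rmse"`); ties are broken toward the smaller,
#' more parsimonious count.
#'
#' @param cv A `cv_result`.
#' @return Integer LV count.
#' @export
select_lv <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  err <- if (cv$select_metric == "rmse") cv$rmse else cv$misclass
  which.min(err)  # which.min returns the first (smallest-A) minimum
}

#' Summarise a cross-validated model as a report row
#'
#' The machine-readable twin of a classification-accuracy table entry:
#' model family label, overall accuracy, selected LV count, and the
#' row-normalised confusion percentages (damaged called damaged / healthy;
#' healthy called damaged / healthy). Percentages are rounded to integers
#' here, at the reporting boundary only; the underlying `cv_result` keeps
#' raw fractions.
#'
#' @param cv A `cv_result`.
#' @param label Model family label, e.g. `"MIR+NIR"`.
#' @return One-row data frame with columns `model`, `accuracy`, `lv`,
#'   `sensitivity`, `specificity`, `damaged_as_damaged`,
#'   `damaged_as_healthy`, `healthy_as_damaged`, `healthy_as_healthy`,
#'   `n_damaged`, `n_healthy`.
#' @export
report <- function(cv, label = "model") {
  stopifnot(inherits(cv, "cv_result"))
  s <- cv$stats
  data.frame(
    model = label,
    accuracy = round(100 * s$accuracy),
    lv = cv$chosen_a,
    sensitivity = round(100 * s$sensitivity),
    specificity = round(100 * s$specificity),
    damaged_as_damaged = round(100 * s$sensitivity),
    damaged_as_healthy = round(100 * (1 - s$sensitivity)),
    healthy_as_damaged = round(100 * (1 - s$specificity)),
    healthy_as_healthy = round(100 * s$specificity),
    n_damaged = s$n1, n_healthy = s$n0,
    row.names = NULL)
}
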