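#' Frobenius-norm block scaling
#'
#' Divides each block elementwise by its Frobenius norm (the square root of
#' the sum of squared matrix entries), computed over the supplied
#' (training) rows of the uncentered preprocessed intensities. This sets
#' blocks from different instruments on the same footing so no block
#' dominates the fusion merely through its numeric scale. The norms are
#' returned so the same divisors can be applied to test rows.
#'
#' @param blocks A `block_set` (or list of aligned `spectral_block`s).
#' @return List with `blocks` (the scaled `block_set`) and `norms` (named
#'   numeric vector).
#' @export
frobenius_scale <- function(blocks) {
  bs <- block_set(blocks)
  norms <- vapply(bs$blocks, function(b) sqrt(sum(b$intensities^2)),
                  numeric(1))
  if (any(norms == 0))
    stop("zero-Frobenius-norm block: ",
         paste(names(bs$blocks)[norms == 0], collapse = ", "))
  bs$blocks <- mapply(function(b, nm) {
    block_update(b, b$intensities / nm, step = "frobenius_scale")
  }, bs$blocks, norms, SIMPLIFY = FALSE)
  list(blocks = bs, norms = norms)
}

#' Fit a multi-block PLS-DA model
#'
#' Scaled-concatenation MB-PLS: each preprocessed block is normalised by its
#' Frobenius norm, the blocks are concatenated into one super-matrix, and a
#' single PLS1 model is fitted on it, yielding one global score vector per
#' latent variable. Block importance per LV is extracted post hoc from the
#' super-weight vector `w_a`: the weight of block `j` is the share of
#' `||w_a||^2` carried by that block's channels, so each column of
#' `block_weights` sums to 1.
#'
#' @param blocks A `block_set` or named list of aligned preprocessed
#'   `spectral_block`s (one entry degenerates to plain PLS-DA).
#' @param y 0/1 class vector aligned with the block rows.
#' @param A Number of latent variables.
#' @return An object of class `mbpls_model`: `inner` (the `pls_model` on the
#'   scaled super-matrix), `block_norms`, `block_weights`
#'   (blocks x A matrix), `boundaries`, `axes` and `modalities`.
#' @export
fit_mbpls <- function(blocks, y, A) {
  bs <- block_set(blocks)
  sc <- frobenius_scale(bs)
  Xs <- concat_blocks(sc$blocks)
  inner <- fit_pls(Xs, y, A, row_keys = bs$blocks[[1]]$row_keys)
  nb <- nrow(bs$boundaries)
  eff <- inner$n_lv_effective
  bw <- matrix(0, nb, eff,
               dimnames = list(bs$boundaries$modality, NULL))
  for (a in seq_len(eff)) {
    w <- inner$W[, a]
    tot <- sum(w^2)
    for (j in seq_len(nb))
      bw[j, a] <- sum(w[bs$boundaries$lo[j]:bs$boundaries$hi[j]]^2) / tot
  }
  structure(
    list(inner = inner, block_norms = sc$norms, block_weights = bw,
         boundaries = bs$boundaries,
         axes = lapply(bs$blocks, function(b) b$axis),
         modalities = bs$boundaries$modality),
    class = "mbpls_model")
}

#' @export
print.mbpls_model <- function(x, ...) {
  cat("<mbpls_model> ", paste(x$modalities, collapse = " + "), ", ",
      x$inner$n_lv, " latent variable(s)\n", sep = "")
  cat("  block weights (LV1):",
      paste(sprintf("%s=%.2f", x$modalities, x$block_weights[, 1]),
            collapse = " "), "\n")
  invisible(x)
}

#' Predict continuous class scores from a multi-block model
#'
#' New blocks are divided by the training Frobenius norms, concatenated and
#' pushed through the inner PLS model.
#'
#' @param object An `mbpls_model`.
#' @param newblocks A `block_set` (or list) with the model's modalities.
#' @param n_lv Number of latent variables to use.
#' @param ... Unused.
#' @return Numeric vector of continuous scores.
#' @export
predict.mbpls_model <- function(object, newblocks,
                                n_lv = object$inner$n_lv, ...) {
  bs <- block_set(newblocks)
  if (!identical(as.character(bs$boundaries$modality),
                 as.character(object$modalities)))
    stop("modalities of newblocks do not match the model (",
         paste(object$modalities, collapse = ", "), ")")
  Xs <- do.call(cbind, mapply(function(b, nm) b$intensities / nm,
                              bs$blocks, object$block_norms,
                              SIMPLIFY = FALSE))
  predict(object$inner, Xs, n_lv = n_lv)
}

#' Correlation loadings of variables with a pair of global scores
#'
#' Pearson correlation of each supplied variable (a spectral channel, a
#' treatment-group dummy, or any row-aligned covariate) with two global
#' score vectors of the model, the coordinates of a correlation loading
#' plot. Points near the unit circle are fully explained by the two latent
#' variables; the conventional inner reference circle at r = 0.5 marks 25%
#' explained variance. A zero-variance variable has no defined correlation
#' and is reported as missing (`NA`), not zero.
#'
#' @param model An `mbpls_model` (or `pls_model` with scores `T`).
#' @param variables Matrix or data frame, rows aligned with the model's
#'   training rows, one column per variable.
#' @param lv_pair Integer pair of latent variables (default `c(1, 2)`).
#' @return Data frame with columns `variable`, `r1`, `r2`; attribute
#'   `radii = c(0.5, 1)` carries the reference circle radii.
#' @export
correlation_loadings <- function(model, variables, lv_pair = c(1, 2)) {
  scores <- if (inherits(model, "mbpls_model")) model$inner$T else model$T
  if (max(lv_pair) > ncol(scores))
    stop("model has only ", ncol(scores), " latent variable(s); cannot use ",
         "LV pair (", lv_pair[1], ", ", lv_pair[2], ")")
  V <- as.matrix(variables)
  if (nrow(V) != nrow(scores))
    stop("variables must be row-aligned with the ", nrow(scores),
         " training rows")
  nm <- colnames(V)
  if (is.null(nm)) nm <- paste0("V", seq_len(ncol(V)))
  safe_cor <- function(v, s) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(v, s)
  }
  out <- data.frame(
    variable = nm,
    r1 = apply(V, 2, safe_cor, s = scores[, lv_pair[1]]),
    r2 = apply(V, 2, safe_cor, s = scores[, lv_pair[2]]),
    row.names = NULL)
  attr(out, "radii") <- c(0.5, 1)
  attr(out, "lv_pair") <- lv_pair
  out
}
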