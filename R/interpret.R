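#' Per-block regression coefficients on the preprocessed scale
#'
#' Slices the super-matrix regression coefficients of a multi-block model by
#' the block boundaries and divides each slice by its block's Frobenius
#' norm, so the coefficients apply directly to preprocessed-but-unscaled
#' spectra. The concatenation of the unscaled slices reproduces the model's
#' predictions exactly.
#'
#' @param model An `mbpls_model`.
#' @param n_lv LV count whose nested coefficient vector to use (default:
#'   all fitted).
#' @return Named list (per modality) of numeric coefficient vectors.
#' @export
unscaled_block_coefficients <- function(model, n_lv = model$inner$n_lv) {
  stopifnot(inherits(model, "mbpls_model"))
  b <- model$inner$B[, n_lv]
  out <- list()
  for (j in seq_len(nrow(model$boundaries))) {
    nm <- model$boundaries$modality[j]
    idx <- model$boundaries$lo[j]:model$boundaries$hi[j]
    out[[nm]] <- b[idx] / model$block_norms[[nm]]
  }
  out
}

#' Pre-select discriminative bands from regression coefficients
#'
#' The variables entering a correlation loading plot are the spectral bands
#' with the largest regression-coefficient magnitudes. Candidate bands are
#' the local extrema of |b| along each modality's axis (strict neighbour
#' comparison; on a plateau the leftmost channel is taken); the top `k` per
#' block by |b| are kept. Axis endpoints qualify when they exceed their
#' single neighbour. On finely sampled axes, noise produces clusters of
#' quasi-duplicate extrema a fraction of a band width apart; extrema are
#' therefore accepted greedily in decreasing |b| order, skipping any
#' candidate closer than `min_separation` (cm^-1) to an already accepted
#' band, so the k slots go to k distinct bands.
#'
#' @param coeffs Named list of per-block coefficient vectors (see
#'   [unscaled_block_coefficients()]).
#' @param axes Named list of wavenumber axes matching `coeffs`.
#' @param k_per_block Bands to keep per modality (fewer if the modality has
#'   fewer extrema; no padding).
#' @param min_separation Minimum wavenumber distance (cm^-1) between
#'   selected bands of one modality; 0 disables deduplication.
#' @return An object of class `peak_selection`: data frame with columns
#'   `modality`, `wavenumber`, `channel`, `coefficient`, `rank` (per
#'   modality, by |coefficient|), sorted by modality then rank.
#' @export
select_peaks <- function(coeffs, axes, k_per_block = 12L,
                         min_separation = 10) {
  stopifnot(k_per_block >= 1)
  if (!identical(names(coeffs), names(axes)))
    stop("coeffs and axes must share modality names")
  rows <- list()
  for (nm in names(coeffs)) {
    b <- abs(coeffs[[nm]])
    p <- length(b)
    if (p != length(axes[[nm]]))
      stop("coefficient length does not match axis for '", nm, "'")
    is_ext <- logical(p)
    for (i in seq_len(p)) {
      left_ok <- i == 1L || b[i] > b[i - 1L]
      right_ok <- i == p || b[i] > b[i + 1L]
      # plateau: leftmost channel of a flat top counts, later ones do not
      plateau_right <- i < p && b[i] == b[i + 1L] &&
        (i == 1L || b[i] > b[i - 1L]) && plateau_exceeds(b, i)
      is_ext[i] <- (left_ok && right_ok) || plateau_right
    }
    idx <- which(is_ext)
    if (!length(idx)) next
    idx <- idx[order(b[idx], decreasing = TRUE)]
    ax <- axes[[nm]]
    picked <- integer(0)
    for (i in idx) {
      if (length(picked) == k_per_block) break
      if (!length(picked) ||
          all(abs(ax[picked] - ax[i]) >= min_separation))
        picked <- c(picked, i)
    }
    idx <- picked
    rows[[nm]] <- data.frame(
      modality = nm, wavenumber = axes[[nm]][idx], channel = idx,
      coefficient = coeffs[[nm]][idx],
      rank = seq_along(idx))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_selection", "data.frame")
  out
}

# Does the plateau starting at i end by dropping below b[i] (true summit)
# rather than rising above it?
plateau_exceeds <- function(b, i) {
  j <- i + 1L
  while (j <= length(b) && b[j] == b[i]) j <- j + 1L
  j > length(b) || b[j] < b[i]
}

#' Assemble the correlation loading plot table
#'
#' Computes correlation loadings (see [correlation_loadings()]) for the
#' selected spectral bands — taken from the preprocessed, unscaled blocks —
#' together with one 0/1 dummy per damage subgroup (E1, E2, E3, M1, M2)
#' treated as a supplementary design variable: the dummies are correlated
#' with the global scores post hoc, never refitted into the model, which is
#' trained on damaged-vs-healthy only. Points with `r1^2 + r2^2 < 0.25`
#' fall inside the inner reference circle and are flagged as not well
#' explained by the chosen LV pair.
#'
#' @param model An `mbpls_model` with at least 2 latent variables.
#' @param blocks The preprocessed sample-level `block_set` the model was
#'   trained on.
#' @param design Study design covering the block rows (`subgroup` column
#'   supplies the dummies; controls carry no dummy).
#' @param selection A `peak_selection`.
#' @param lv_pair LV pair for the plot (default `c(1, 2)`).
#' @return Data frame with columns `label`, `kind` (`"spectral"` /
#'   `"design"`), `modality`, `wavenumber`, `r1`, `r2`,
#'   `inside_inner_circle`; attribute `radii = c(0.5, 1)`.
#' @export
correlation_plot_table <- function(model, blocks, design, selection,
                                   lv_pair = c(1, 2)) {
  stopifnot(inherits(model, "mbpls_model"))
  if (model$inner$n_lv_effective < max(lv_pair))
    stop("model needs at least ", max(lv_pair), " latent variables")
  bs <- block_set(blocks)
  design <- validate_design(design)
  keys <- bs$blocks[[1]]$row_keys
  dmap <- design$subgroup[match(keys$sample_id, design$sample_id)]

  cols <- list(); meta <- list()
  for (i in seq_len(nrow(selection))) {
    nm <- selection$modality[i]
    ch <- selection$channel[i]
    cols[[length(cols) + 1L]] <- bs$blocks[[nm]]$intensities[, ch]
    meta[[length(meta) + 1L]] <- data.frame(
      label = sprintf("%s %g", nm, selection$wavenumber[i]),
      kind = "spectral", modality = nm,
      wavenumber = selection$wavenumber[i])
  }
  subgroups <- sort(setdiff(unique(design$subgroup), "control"))
  for (sg in subgroups) {
    cols[[length(cols) + 1L]] <- as.numeric(dmap == sg)
    meta[[length(meta) + 1L]] <- data.frame(
      label = sg, kind = "design", modality = NA_character_,
      wavenumber = NA_real_)
  }
  V <- do.call(cbind, cols)
  meta <- do.call(rbind, meta)
  colnames(V) <- meta$label
  cl <- correlation_loadings(model, V, lv_pair)
  out <- cbind(meta, cl[, c("r1", "r2")])
  out$inside_inner_circle <- ifelse(
    is.na(out$r1) | is.na(out$r2), NA, out$r1^2 + out$r2^2 < 0.25)
  rownames(out) <- NULL
  attr(out, "radii") <- c(0.5, 1)
  attr(out, "lv_pair") <- lv_pair
  out
}

#' Plot a correlation loading table
#'
#' Scatter of `(r1, r2)` with the unit and r = 0.5 reference circles;
#' spectral bands coloured by modality, design dummies in purple.
#'
#' @param tab Output of [correlation_plot_table()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `tab`.
#' @export
plot_correlation_loadings <- function(tab, ...) {
  lv <- attr(tab, "lv_pair"); if (is.null(lv)) lv <- c(1, 2)
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1,
                 xlab = sprintf("Correlation with LV%d scores", lv[1]),
                 ylab = sprintf("Correlation with LV%d scores", lv[2]), ...)
  th <- seq(0, 2 * pi, length.out = 200)
  for (r in attr(tab, "radii"))
    graphics::lines(r * cos(th), r * sin(th), lty = if (r < 1) 3 else 1,
                    col = if (r < 1) "red" else "blue")
  mods <- unique(stats::na.omit(tab$modality))
  pal <- grDevices::hcl.colors(max(length(mods), 3), "Dark 3")
  col <- ifelse(tab$kind == "design", "purple",
                pal[match(tab$modality, mods)])
  graphics::points(tab$r1, tab$r2, col = col, pch = 19)
  graphics::text(tab$r1, tab$r2, tab$label, pos = 3, cex = 0.6, col = col)
  invisible(tab)
}
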