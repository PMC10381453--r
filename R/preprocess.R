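#' Define a preprocessing specification for one modality
#'
#' Bundles the five preprocessing categories applied to each spectral block
#' before modelling: clipping (deleting wavenumber regions), Savitzky-Golay
#' smoothing/derivation, standard normal variate (SNV) row normalisation,
#' and trimming to the informative wavenumber window. The stage order is
#' configurable; the default `clip -> sg -> snv -> trim` derives on the wide
#' untrimmed axis so the (possibly large) filter window never runs against
#' the edges of the analysis window.
#'
#' @param deriv_order Derivative order: 0 (smoothing only), 1 or 2.
#' @param sg_window Savitzky-Golay filter window, odd number of channels.
#' @param sg_polyorder Polynomial order of the local fit; must exceed
#'   `deriv_order` or equal it, and be smaller than `sg_window`.
#' @param apply_snv Apply SNV after derivation?
#' @param trim_lo,trim_hi Trimming bounds in cm^-1 (closed interval);
#'   descending bounds are normalised.
#' @param clip_regions Optional list of `c(lo, hi)` wavenumber regions to
#'   delete before anything else (spike/detector-edge removal); default none.
#' @param stage_order Character vector ordering the stages; subset of
#'   `c("clip", "sg", "snv", "trim")`.
#' @return An object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(deriv_order = 0L, sg_window = 5L,
                            sg_polyorder = 3L, apply_snv = TRUE,
                            trim_lo = -Inf, trim_hi = Inf,
                            clip_regions = NULL,
                            stage_order = c("clip", "sg", "snv", "trim")) {
  if (trim_lo > trim_hi) { tmp <- trim_lo; trim_lo <- trim_hi; trim_hi <- tmp }
  spec <- structure(
    list(deriv_order = as.integer(deriv_order),
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         apply_snv = isTRUE(apply_snv),
         trim_lo = trim_lo, trim_hi = trim_hi,
         clip_regions = clip_regions,
         stage_order = stage_order),
    class = "preprocess_spec")
  if (spec$sg_window %% 2L == 0L) stop("sg_window must be odd")
  if (spec$sg_polyorder >= spec$sg_window)
    stop("sg_polyorder must be smaller than sg_window")
  if (spec$deriv_order > spec$sg_polyorder)
    stop("deriv_order must not exceed sg_polyorder")
  if (!spec$deriv_order %in% 0:2) stop("deriv_order must be 0, 1 or 2")
  if (!all(stage_order %in% c("clip", "sg", "snv", "trim")))
    stop("unknown stage in stage_order")
  spec
}

#' Per-modality preprocessing defaults
#'
#' The parameterisations used for the cartilage study: MIR second derivative
#' (window 201, polynomial order 3) with SNV, trimmed to 900--1800 cm^-1;
#' NIR smoothing only (window 5, order 3) with SNV, trimmed to
#' 4545--8333 cm^-1; Raman first derivative (window 205, order 3) with SNV,
#' trimmed to 800--1800 cm^-1.
#'
#' @return Named list of `preprocess_spec` (MIR, NIR, Raman).
#' @export
default_preprocess_specs <- function() {
  list(
    MIR = preprocess_spec(deriv_order = 2L, sg_window = 201L,
                          sg_polyorder = 3L, apply_snv = TRUE,
                          trim_lo = 900, trim_hi = 1800),
    NIR = preprocess_spec(deriv_order = 0L, sg_window = 5L,
                          sg_polyorder = 3L, apply_snv = TRUE,
                          trim_lo = 4545, trim_hi = 8333),
    Raman = preprocess_spec(deriv_order = 1L, sg_window = 205L,
                            sg_polyorder = 3L, apply_snv = TRUE,
                            trim_lo = 800, trim_hi = 1800))
}

#' Savitzky-Golay smoothing / derivation
#'
#' Fits, per spectrum, a local least-squares polynomial of the stated order
#' over a sliding window and returns the fit (derivative order 0) or its
#' derivative with respect to channel index. Edge channels are evaluated
#' from the polynomial fitted over the nearest full window, so output length
#' equals input length and polynomials up to `sg_polyorder` are reproduced
#' exactly everywhere.
#'
#' @param block A `spectral_block`.
#' @param spec A `preprocess_spec` (fields `deriv_order`, `sg_window`,
#'   `sg_polyorder` are used).
#' @return The filtered block.
#' @export
savitzky_golay <- function(block, spec) {
  stopifnot(inherits(block, "spectral_block"),
            inherits(spec, "preprocess_spec"))
  p <- length(block$axis)
  if (spec$sg_window > p)
    stop("sg_window (", spec$sg_window, ") exceeds channel count (", p,
         ") of block '", block$modality, "'")
  if (spec$sg_window %% 2L == 0L) stop("sg_window must be odd")
  filt <- signal::sgolay(p = spec$sg_polyorder, n = spec$sg_window,
                         m = spec$deriv_order, ts = 1)
  out <- t(apply(block$intensities, 1,
                 function(r) signal::sgolayfilt(r, filt)))
  block_update(block, out,
               step = sprintf("sg(deriv=%d,window=%d,poly=%d)",
                              spec$deriv_order, spec$sg_window,
                              spec$sg_polyorder))
}

#' Standard normal variate (SNV)
#'
#' Centers every spectrum to mean zero and scales it to unit sample standard
#' deviation (denominator n - 1), removing additive offsets and
#' multiplicative scatter differences between spectra. Purely row-local:
#' no information crosses spectra.
#'
#' @param block A `spectral_block` with at least 2 channels per row.
#' @return The normalised block.
#' @export
snv <- function(block) {
  stopifnot(inherits(block, "spectral_block"))
  if (length(block$axis) < 2) stop("SNV needs at least 2 channels")
  mu <- rowMeans(block$intensities)
  sdv <- apply(block$intensities, 1, stats::sd)
  bad <- which(sdv == 0 | !is.finite(sdv))
  if (length(bad)) {
    k <- block$row_keys[bad[1], ]
    stop("constant spectrum (zero spread) in block '", block$modality,
         "' at sample_id=", k$sample_id, " replicate=", k$replicate)
  }
  block_update(block, (block$intensities - mu) / sdv, step = "snv")
}

#' Trim a block to a wavenumber window
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi` (closed
#' interval). Bounds given in descending order (as NIR windows are often
#' printed) are normalised.
#'
#' @param block A `spectral_block`.
#' @param lo,hi Window bounds in cm^-1.
#' @return The trimmed block.
#' @export
trim_block <- function(block, lo, hi) {
  stopifnot(inherits(block, "spectral_block"))
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  keep <- block$axis >= lo & block$axis <= hi
  if (!any(keep))
    stop("trim window [", lo, ", ", hi, "] retains no channels of block '",
         block$modality, "'")
  block_update(block, block$intensities[, keep, drop = FALSE],
               axis = block$axis[keep],
               step = sprintf("trim(%g,%g)", lo, hi))
}

#' Clip (delete) wavenumber regions from a block
#'
#' Removes all channels falling inside any of the given closed intervals —
#' the hook for spike or detector-edge removal. With `regions = NULL`
#' (the default spec) the block passes through unchanged.
#'
#' @param block A `spectral_block`.
#' @param regions List of `c(lo, hi)` intervals to delete, or `NULL`.
#' @return The clipped block.
#' @export
clip_block <- function(block, regions = NULL) {
  stopifnot(inherits(block, "spectral_block"))
  if (is.null(regions) || !length(regions)) return(block)
  drop <- rep(FALSE, length(block$axis))
  for (rg in regions) {
    rg <- sort(as.numeric(rg))
    drop <- drop | (block$axis >= rg[1] & block$axis <= rg[2])
  }
  if (all(drop)) stop("clipping removes every channel of block '",
                      block$modality, "'")
  block_update(block, block$intensities[, !drop, drop = FALSE],
               axis = block$axis[!drop],
               step = sprintf("clip(%d region(s))", length(regions)))
}

#' Apply a full preprocessing specification to a block
#'
#' Runs the spec's stages in its `stage_order` (default
#' clip -> Savitzky-Golay -> SNV -> trim) and records each applied stage in
#' the block's provenance attribute.
#'
#' @param block A `spectral_block`.
#' @param spec A `preprocess_spec`.
#' @return The preprocessed block.
#' @export
preprocess_block <- function(block, spec) {
  stopifnot(inherits(block, "spectral_block"),
            inherits(spec, "preprocess_spec"))
  for (stage in spec$stage_order) {
    block <- switch(stage,
      clip = clip_block(block, spec$clip_regions),
      sg   = savitzky_golay(block, spec),
      snv  = if (spec$apply_snv) snv(block) else block,
      trim = trim_block(block, spec$trim_lo, spec$trim_hi))
  }
  block
}

#' Average replicate spectra into one row per sample
#'
#' Model rows must be samples for leave-one-joint-out cross-validation to be
#' well defined; replicates are preprocessed individually and then averaged.
#' Output rows follow the order of first appearance of each sample.
#'
#' @param block A `spectral_block` with replicate rows.
#' @return A `spectral_block` with one row per sample (`replicate = 0`).
#' @export
average_replicates <- function(block) {
  stopifnot(inherits(block, "spectral_block"))
  ids <- unique(block$row_keys$sample_id)
  X <- matrix(0, length(ids), length(block$axis))
  for (i in seq_along(ids)) {
    rows <- block$row_keys$sample_id == ids[i]
    X[i, ] <- colMeans(block$intensities[rows, , drop = FALSE])
  }
  out <- spectral_block(block$modality, block$axis, X,
                        data.frame(sample_id = ids, replicate = 0L))
  attr(out, "provenance") <- c(attr(block, "provenance"), "average_replicates")
  out
}
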