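#' Construct a spectral block
#'
#' A spectral block holds all spectra of one modality (MIR, NIR or Raman) as a
#' wide matrix: one row per acquired spectrum, one column per wavenumber
#' channel. Rows are linked to the study design through `row_keys`
#' (`sample_id`, `replicate`), which every multi-block operation uses to
#' enforce sample-to-sample correspondence across modalities.
#'
#' @param modality Character label, e.g. `"MIR"`.
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly ascending.
#' @param intensities Numeric matrix, rows = spectra, columns = channels;
#'   `ncol(intensities)` must equal `length(axis)`.
#' @param row_keys Data frame with columns `sample_id` and `replicate`, one
#'   row per spectrum.
#' @return An object of class `spectral_block`.
#' @export
spectral_block <- function(modality, axis, intensities, row_keys) {
  intensities <- as.matrix(intensities)
  axis <- as.numeric(axis)
  if (length(axis) != ncol(intensities))
    stop("axis length (", length(axis), ") must equal channel count (",
         ncol(intensities), ")")
  if (length(axis) >= 2 && any(diff(axis) <= 0))
    stop("axis must be strictly ascending")
  if (!is.data.frame(row_keys) ||
      !all(c("sample_id", "replicate") %in% names(row_keys)))
    stop("row_keys must be a data frame with columns sample_id, replicate")
  if (nrow(row_keys) != nrow(intensities))
    stop("row_keys has ", nrow(row_keys), " rows but intensities has ",
         nrow(intensities))
  if (any(!is.finite(intensities)))
    stop("non-finite intensities in block '", modality, "'")
  dimnames(intensities) <- NULL
  structure(
    list(modality = as.character(modality), axis = axis,
         intensities = intensities,
         row_keys = row_keys[, c("sample_id", "replicate"), drop = FALSE]),
    provenance = character(0),
    class = "spectral_block")
}

#' @export
print.spectral_block <- function(x, ...) {
  cat("<spectral_block> ", x$modality, ": ", nrow(x$intensities),
      " spectra x ", length(x$axis), " channels [",
      format(min(x$axis)), ", ", format(max(x$axis)), "] cm^-1\n", sep = "")
  prov <- attr(x, "provenance")
  if (length(prov)) cat("  preprocessing:", paste(prov, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.spectral_block <- function(x) dim(x$intensities)

# Replace the intensity matrix (and optionally the axis), carrying provenance.
block_update <- function(block, intensities, axis = block$axis, step = NULL) {
  out <- spectral_block(block$modality, axis, intensities, block$row_keys)
  attr(out, "provenance") <- c(attr(block, "provenance"), step)
  out
}

#' Validate a study design table
#'
#' The design table carries the sample-level metadata shared by every block:
#' one row per specimen with its joint of origin, class label
#' (0 = normal cartilage, 1 = damaged cartilage), damage subgroup and the
#' number of replicate spectra acquired.
#'
#' @param design Data frame with columns `sample_id`, `joint_id`, `class`,
#'   `subgroup`.
#' @return The validated design (invisibly the same data frame).
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "joint_id", "class", "subgroup")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop("design must be a data frame with columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design")
  if (!all(design$class %in% c(0L, 1L)))
    stop("class must be 0 (normal) or 1 (damaged)")
  design
}

#' Bind preprocessed blocks into an aligned block set
#'
#' Multi-block analysis requires sample-to-sample correspondence between
#' blocks: every block must contain the same rows (same `sample_id` and
#' `replicate`) in the same order. `block_set` checks this and records the
#' column ranges each block occupies in the concatenated super-matrix.
#'
#' @param blocks Named list of `spectral_block` objects (names = modalities).
#' @return An object of class `block_set` with elements `blocks` and
#'   `boundaries` (per-block first/last column in the concatenation).
#' @export
block_set <- function(blocks) {
  if (inherits(blocks, "block_set")) return(blocks)
  if (inherits(blocks, "spectral_block")) blocks <- list(blocks)
  if (!length(blocks)) stop("empty block list")
  if (is.null(names(blocks)) || any(!nzchar(names(blocks))))
    names(blocks) <- vapply(blocks, function(b) b$modality, character(1))
  keys0 <- blocks[[1]]$row_keys
  for (b in blocks[-1]) {
    if (nrow(b$row_keys) != nrow(keys0) ||
        !all(b$row_keys$sample_id == keys0$sample_id) ||
        !all(b$row_keys$replicate == keys0$replicate))
      stop("blocks '", blocks[[1]]$modality, "' and '", b$modality,
           "' do not have identical row keys: sample-to-sample ",
           "correspondence between blocks is required")
  }
  p <- vapply(blocks, function(b) length(b$axis), integer(1))
  hi <- cumsum(p)
  lo <- hi - p + 1L
  boundaries <- data.frame(modality = names(blocks), lo = lo, hi = hi,
                           row.names = NULL)
  structure(list(blocks = blocks, boundaries = boundaries),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat("<block_set> ", length(x$blocks), " block(s), ",
      nrow(x$blocks[[1]]$intensities), " rows\n", sep = "")
  for (i in seq_along(x$blocks))
    cat("  ", format(names(x$blocks)[i], width = 8),
        " columns ", x$boundaries$lo[i], "-", x$boundaries$hi[i], "\n",
        sep = "")
  invisible(x)
}

# Concatenate a block set into the super-matrix.
concat_blocks <- function(bs) {
  do.call(cbind, lapply(bs$blocks, function(b) b$intensities))
}
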