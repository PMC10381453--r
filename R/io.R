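#' Write a spectral block as delimited text
#'
#' Wide-matrix layout: columns `sample_id`, `replicate`, then one column per
#' wavenumber channel with the wavenumber as the header.
#'
#' @param block A `spectral_block`.
#' @param path Output file (CSV).
#' @return Invisibly, `path`.
#' @export
write_block <- function(block, path) {
  stopifnot(inherits(block, "spectral_block"))
  dt <- data.table::as.data.table(block$intensities)
  data.table::setnames(dt, as.character(block$axis))
  dt <- cbind(data.table::as.data.table(block$row_keys), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a spectral block from delimited text
#'
#' Accepts any wide matrix whose header row carries the wavenumbers, with
#' leading `sample_id` and `replicate` columns as written by
#' [write_block()] (a missing `replicate` column defaults to 1).
#'
#' @param path Input file.
#' @param modality Modality label for the block.
#' @return A `spectral_block`.
#' @export
read_block <- function(path, modality) {
  dt <- data.table::fread(path)
  if (!"sample_id" %in% names(dt))
    stop("block file must contain a sample_id column: ", path)
  if (!"replicate" %in% names(dt)) dt$replicate <- 1L
  keys <- data.frame(sample_id = as.character(dt$sample_id),
                     replicate = as.integer(dt$replicate))
  wn_cols <- setdiff(names(dt), c("sample_id", "replicate"))
  axis <- as.numeric(wn_cols)
  if (any(is.na(axis)))
    stop("non-numeric wavenumber headers in ", path)
  ord <- order(axis)
  X <- as.matrix(dt[, wn_cols, with = FALSE])[, ord, drop = FALSE]
  spectral_block(modality, axis[ord], X, keys)
}

#' Write / read a study design table
#'
#' @param design Study design data frame.
#' @param path CSV file.
#' @return Invisibly `path`; `read_design()` returns the validated design.
#' @export
write_design <- function(design, path) {
  data.table::fwrite(validate_design(design), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- as.data.frame(data.table::fread(path))
  d$sample_id <- as.character(d$sample_id)
  d$joint_id <- as.character(d$joint_id)
  d$class <- as.integer(d$class)
  validate_design(d)
}

#' Write a full synthetic study to a directory
#'
#' One block file per modality (`blocks/<modality>.csv`), the design table
#' (`design.csv`) and the generating configuration (`config.yaml`).
#'
#' @param study A `synth_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synth_study"))
  dir.create(file.path(dir, "blocks"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$blocks))
    write_block(study$blocks[[nm]], file.path(dir, "blocks",
                                              paste0(nm, ".csv")))
  write_design(study$design, file.path(dir, "design.csv"))
  write_synth_config(study$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Serialise / restore a synthetic-study configuration as YAML
#'
#' @param cfg A `synth_config`.
#' @param path YAML file.
#' @return Invisibly `path`; `read_synth_config()` returns the
#'   `synth_config`.
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  lst <- unclass(cfg)
  # named atomic vectors serialise as sequences (names lost); use mappings
  lst$subgroup_scheme <- as.list(lst$subgroup_scheme)
  lst$subgroup_multipliers <- as.list(lst$subgroup_multipliers)
  lst$modalities <- lapply(lst$modalities, function(m) {
    m$peaks <- as.list(m$peaks)
    m
  })
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$modalities <- lapply(lst$modalities, function(m) {
    m$peaks <- as.data.frame(m$peaks)
    m
  })
  do.call(synth_config, c(
    lst[c("n_joints", "samples_per_joint_per_class", "replicates_per_sample",
          "joint_effect_sd", "replicate_noise_sd", "rng_seed")],
    list(subgroup_scheme = unlist(lst$subgroup_scheme),
         subgroup_multipliers = unlist(lst$subgroup_multipliers),
         modalities = lst$modalities,
         baseline_offset_range = unlist(lst$baseline_offset_range),
         baseline_slope_range = unlist(lst$baseline_slope_range),
         scatter_range = unlist(lst$scatter_range))))
}

#' Serialise a preprocessing spec to / from YAML-ready lists
#'
#' @param spec A `preprocess_spec`.
#' @param path YAML file.
#' @return Invisibly `path`; `read_preprocess_spec()` returns the spec.
#' @export
write_preprocess_spec <- function(spec, path) {
  stopifnot(inherits(spec, "preprocess_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_preprocess_spec
#' @export
read_preprocess_spec <- function(path) {
  do.call(preprocess_spec, yaml::read_yaml(path))
}
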