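#' Configure a synthetic multi-modal spectral study
#'
#' Builds the configuration for [generate_study()]. The defaults emulate the
#' bovine cartilage study design this package's analysis chain targets:
#' 10 joints contributing 6 damaged and 6 adjacent control cylindrical
#' specimens each (60 + 60 samples), damaged samples split evenly over five
#' treatment subgroups (impact M1, abrasion M2, collagenase-24h E1,
#' collagenase-90min E2, trypsin E3), three replicate spectra per sample, and
#' three modalities (MIR, NIR, Raman) whose discriminative Gaussian bands sit
#' at positions reported for cartilage damage (MIR amide/ester bands at 1740,
#' 1655, 1564, 1245 cm^-1; NIR 4726, 4829 cm^-1; Raman 1004, 1250,
#' 1665 cm^-1).
#'
#' Each replicate spectrum is generated as
#' \deqn{s(\nu) = m \sum_k a_k e^{-(\nu - c_k)^2 / 2 w_k^2} + b_0 + b_1 \nu
#'   + \varepsilon(\nu)}
#' with peak amplitude \eqn{a_k = \mathrm{base}_k + \delta_k \cdot
#' \mathrm{class} \cdot \mu_{\mathrm{subgroup}} + u_{\mathrm{joint}}},
#' a multiplicative scatter factor \eqn{m}, a linear baseline and i.i.d.
#' Gaussian channel noise. The joint random effect \eqn{u} is one amplitude
#' shift per (joint, modality) shared by all samples of that joint — the
#' minimal structure that makes leave-one-joint-out cross-validation
#' different from leave-one-sample-out. Scatter and baseline are the
#' artefacts SNV and derivative preprocessing exist to remove.
#'
#' @param n_joints Number of joints (knees) contributing samples.
#' @param samples_per_joint_per_class Damaged (and, equally, control) samples
#'   per joint.
#' @param subgroup_scheme Named numeric vector: fraction of damaged samples
#'   per treatment subgroup; must sum to 1 and yield whole counts.
#' @param replicates_per_sample Replicate spectra acquired per sample.
#' @param modalities Named list; each element has `start`, `end` (cm^-1),
#'   `channels`, and `peaks`, a data frame with columns `center`, `width`
#'   (cm^-1), `base` (amplitude) and `delta` (class effect on amplitude;
#'   0 = non-discriminative band).
#' @param subgroup_multipliers Named numeric vector: multiplier applied to
#'   every peak's `delta` for samples of that subgroup. The default makes E1
#'   (severe collagenase damage) 1.5x stronger than the other treatments.
#' @param joint_effect_sd SD of the per-(joint, modality) amplitude shift.
#' @param replicate_noise_sd SD of i.i.d. channel noise (intensity units).
#' @param baseline_offset_range,baseline_slope_range Uniform ranges for the
#'   additive baseline `b0 + b1 * wavenumber` (slope per cm^-1).
#' @param scatter_range Uniform range of the multiplicative scatter factor.
#' @param rng_seed Integer study seed; all draws derive from it
#'   hierarchically (study -> joint -> sample -> replicate), so removing one
#'   sample never changes another sample's draws.
#' @return An object of class `synth_config`.
#' @seealso [generate_study()], [drop_sample()]
#' @export
synth_config <- function(n_joints = 10L,
                         samples_per_joint_per_class = 6L,
                         subgroup_scheme = c(M1 = 0.2, M2 = 0.2, E1 = 0.2,
                                             E2 = 0.2, E3 = 0.2),
                         replicates_per_sample = 3L,
                         modalities = default_modalities(),
                         subgroup_multipliers = c(M1 = 1, M2 = 1, E1 = 1.5,
                                                  E2 = 1, E3 = 1),
                         joint_effect_sd = 0.05,
                         replicate_noise_sd = 0.02,
                         baseline_offset_range = c(-0.05, 0.05),
                         baseline_slope_range = c(-2e-5, 2e-5),
                         scatter_range = c(0.9, 1.1),
                         rng_seed = 1L) {
  cfg <- structure(
    list(n_joints = as.integer(n_joints),
         samples_per_joint_per_class = as.integer(samples_per_joint_per_class),
         subgroup_scheme = subgroup_scheme,
         replicates_per_sample = as.integer(replicates_per_sample),
         modalities = modalities,
         subgroup_multipliers = subgroup_multipliers,
         joint_effect_sd = joint_effect_sd,
         replicate_noise_sd = replicate_noise_sd,
         baseline_offset_range = baseline_offset_range,
         baseline_slope_range = baseline_slope_range,
         scatter_range = scatter_range,
         rng_seed = as.integer(rng_seed)),
    class = "synth_config")
  validate_synth_config(cfg)
}

#' Default modality axis and peak specifications
#'
#' Axis ranges follow the instruments' acquisition ranges (MIR 400--4000,
#' NIR 4000--10000, Raman 200--3400 cm^-1). Channel spacing matters because
#' the Savitzky-Golay windows are stated in channels: MIR and Raman use
#' 0.25 cm^-1 spacing, close to the FTIR digital spacing, so a 201- or
#' 205-channel window spans a physically sensible ~50 cm^-1; NIR uses
#' 6 cm^-1 (its window is only 5 channels). Bands carrying a nonzero class
#' effect sit at the
#' wavenumbers reported as discriminative for cartilage damage; the
#' remaining bands are stable tissue background.
#'
#' @return Named list suitable for the `modalities` field of
#'   [synth_config()].
#' @export
default_modalities <- function() {
  list(
    MIR = list(
      start = 400, end = 4000, channels = 14401L,
      peaks = data.frame(
        center = c(1740, 1655, 1564, 1245, 1080, 1160, 1338, 1448,
                   2850, 2920, 3300),
        width  = c(16, 20, 18, 22, 25, 20, 15, 16, 20, 30, 90),
        base   = c(0.9, 1.1, 0.9, 0.7, 0.8, 0.5, 0.5, 0.6,
                   0.4, 0.5, 1.0),
        delta  = c(0.12, -0.10, 0.10, 0.10, 0, 0, 0, 0, 0, 0, 0))),
    NIR = list(
      start = 4000, end = 10000, channels = 1001L,
      peaks = data.frame(
        center = c(4726, 4829, 4360, 5200, 5600, 6900, 8500),
        width  = c(35, 35, 60, 160, 200, 140, 300),
        base   = c(0.8, 0.7, 0.7, 1.2, 0.6, 0.9, 0.4),
        delta  = c(0.12, 0.10, 0, 0, 0, 0, 0))),
    Raman = list(
      start = 200, end = 3400, channels = 12801L,
      peaks = data.frame(
        center = c(1004, 1250, 1665, 856, 938, 1062, 1448, 2885, 2940),
        width  = c(8, 16, 14, 10, 10, 12, 14, 25, 30),
        base   = c(1.0, 0.7, 0.9, 0.6, 0.6, 0.5, 0.9, 0.9, 1.1),
        delta  = c(0.10, 0.08, -0.12, 0, 0, 0, 0, 0, 0))))
}

validate_synth_config <- function(cfg) {
  if (cfg$n_joints < 2L) stop("need at least 2 joints")
  if (abs(sum(cfg$subgroup_scheme) - 1) > 1e-9)
    stop("subgroup fractions must sum to 1 over damaged samples")
  n_damaged <- cfg$n_joints * cfg$samples_per_joint_per_class
  counts <- cfg$subgroup_scheme * n_damaged
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("subgroup fractions do not yield whole sample counts at n = ",
         n_damaged)
  if (!length(cfg$modalities)) stop("at least one modality required")
  for (nm in names(cfg$modalities)) {
    m <- cfg$modalities[[nm]]
    if (m$channels < 8L)
      stop("modality '", nm, "': channel count must be >= 8")
    if (!nrow(m$peaks))
      stop("modality '", nm, "': peak table must contain at least one peak")
    bad <- m$peaks$center < m$start | m$peaks$center > m$end
    if (any(bad))
      stop("modality '", nm, "': peak center(s) ",
           paste(m$peaks$center[bad], collapse = ", "),
           " outside axis range [", m$start, ", ", m$end, "]")
    if (any(m$peaks$width <= 0)) stop("peak widths must be positive")
  }
  if (!all(names(cfg$subgroup_scheme) %in% names(cfg$subgroup_multipliers)))
    stop("every subgroup needs an entry in subgroup_multipliers")
  cfg
}

# Build the sample-level design table for a configuration. Damaged samples
# are assigned to subgroups in an interleaved order (within-joint position
# varies fastest) so every subgroup is spread across joints.
build_design <- function(cfg) {
  spj <- cfg$samples_per_joint_per_class
  joints <- sprintf("J%02d", seq_len(cfg$n_joints))
  dmg <- expand.grid(pos = seq_len(spj), joint = joints,
                     stringsAsFactors = FALSE)
  dmg <- dmg[order(dmg$pos, dmg$joint), ]
  labels <- rep(names(cfg$subgroup_scheme),
                round(cfg$subgroup_scheme * nrow(dmg)))
  dmg$subgroup <- labels
  design <- do.call(rbind, lapply(seq_len(cfg$n_joints), function(j) {
    jid <- joints[j]
    sub_j <- dmg$subgroup[dmg$joint == jid][order(dmg$pos[dmg$joint == jid])]
    rbind(
      data.frame(sample_id = sprintf("%s_D%d", jid, seq_len(spj)),
                 joint_id = jid, class = 1L, subgroup = sub_j),
      data.frame(sample_id = sprintf("%s_C%d", jid, seq_len(spj)),
                 joint_id = jid, class = 0L, subgroup = "control"))
  }))
  rownames(design) <- NULL
  validate_design(design)
}

#' Generate a synthetic multi-modal spectral study
#'
#' Draws one complete study from a [synth_config()]: one `spectral_block`
#' per modality with identical row ordering (sample-major, replicates
#' within), the shared design table, and the ground-truth channel sets — per
#' modality, exactly the channels within two widths of a band whose class
#' effect `delta` is nonzero.
#'
#' Reproducibility contract: the same configuration and seed give a
#' bit-identical study, and every sample's draws depend only on the study
#' seed and that sample's own indices.
#'
#' @param cfg A `synth_config`.
#' @return An object of class `synth_study`: list with `blocks` (named list
#'   of `spectral_block`), `design`, `truth` (named list of logical channel
#'   masks) and `config`.
#' @export
generate_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  design <- build_design(cfg)
  n_samp <- nrow(design)
  reps <- cfg$replicates_per_sample
  joint_index <- match(design$joint_id, unique(design$joint_id))
  mult <- ifelse(design$class == 1L,
                 cfg$subgroup_multipliers[design$subgroup], 0)

  blocks <- list()
  truth <- list()
  for (mi in seq_along(cfg$modalities)) {
    mname <- names(cfg$modalities)[mi]
    m <- cfg$modalities[[mi]]
    axis <- seq(m$start, m$end, length.out = m$channels)
    # channels x peaks Gaussian design
    G <- exp(-outer(axis, m$peaks$center, "-")^2 /
               rep(2 * m$peaks$width^2, each = length(axis)))
    joint_eff <- vapply(seq_len(cfg$n_joints), function(j)
      with_local_seed(derive_seed(cfg$rng_seed, 101L, mi, j),
                      stats::rnorm(1, 0, cfg$joint_effect_sd)),
      numeric(1))
    X <- matrix(0, n_samp * reps, length(axis))
    keys <- data.frame(sample_id = rep(design$sample_id, each = reps),
                       replicate = rep(seq_len(reps), times = n_samp))
    row <- 0L
    for (si in seq_len(n_samp)) {
      amp <- m$peaks$base + m$peaks$delta * mult[si] + joint_eff[joint_index[si]]
      clean <- as.vector(G %*% amp)
      for (r in seq_len(reps)) {
        row <- row + 1L
        X[row, ] <- with_local_seed(
          derive_seed(cfg$rng_seed, 202L, mi, si, r), {
            msc <- stats::runif(1, cfg$scatter_range[1], cfg$scatter_range[2])
            b0 <- stats::runif(1, cfg$baseline_offset_range[1],
                               cfg$baseline_offset_range[2])
            b1 <- stats::runif(1, cfg$baseline_slope_range[1],
                               cfg$baseline_slope_range[2])
            eps <- stats::rnorm(length(axis), 0, cfg$replicate_noise_sd)
            msc * clean + b0 + b1 * axis + eps
          })
      }
    }
    blocks[[mname]] <- spectral_block(mname, axis, X, keys)
    tr <- rep(FALSE, length(axis))
    for (k in which(m$peaks$delta != 0))
      tr <- tr | abs(axis - m$peaks$center[k]) <= 2 * m$peaks$width[k]
    truth[[mname]] <- tr
  }
  structure(list(blocks = blocks, design = design, truth = truth,
                 config = cfg),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat("<synth_study> ", nrow(x$design), " samples (",
      sum(x$design$class == 1), " damaged / ", sum(x$design$class == 0),
      " control), ", length(unique(x$design$joint_id)), " joints, ",
      x$config$replicates_per_sample, " replicates\n", sep = "")
  for (b in x$blocks) print(b)
  invisible(x)
}

#' Exclude one sample from every block of a study
#'
#' Removes all replicate spectra of one sample from every modality block and
#' its row from the design, preserving cross-block row correspondence — the
#' bookkeeping used when a sample must be excluded from all blocks (e.g. for
#' poor spectral quality in one modality).
#'
#' @param study A `synth_study`.
#' @param sample_id The sample to remove.
#' @return The study without that sample.
#' @export
drop_sample <- function(study, sample_id) {
  stopifnot(inherits(study, "synth_study"))
  if (!sample_id %in% study$design$sample_id)
    stop("unknown sample id '", sample_id, "'")
  study$design <- study$design[study$design$sample_id != sample_id, ]
  rownames(study$design) <- NULL
  study$blocks <- lapply(study$blocks, function(b) {
    keep <- b$row_keys$sample_id != sample_id
    out <- spectral_block(b$modality, b$axis,
                          b$intensities[keep, , drop = FALSE],
                          b$row_keys[keep, , drop = FALSE])
    attr(out, "provenance") <- attr(b, "provenance")
    out
  })
  study
}
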