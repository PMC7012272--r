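# Synthetic motor-task generator: block-design 4D volumes with a
# soft-edged ellipsoidal brain, class-specific spherical activation added
# as a percent change over a positive voxel-wise baseline, Gaussian noise
# inside the brain mask, and a per-subject baseline multiplier.

#' Synthetic motor-task configuration
#'
#' Describes the simulated scan: volume shape, frames per block, the
#' block layout (3 fixation blocks intermixed with 10 movement blocks, 2
#' per class), the per-class activation amplitude as a percent of
#' baseline, the noise level and the between-subject baseline spread.
#' Each movement class activates one spherical region of interest (ROI);
#' the five centres are fixed, distinct, and spread along all three axes
#' so that every slicing plane carries class information.
#'
#' @param dims Volume shape `(dimX, dimY, dimZ)`.
#' @param frames_per_block Frames in every block; 13 blocks give
#'   `13 * frames_per_block` frames in total.
#' @param amplitude_pct Activation amplitude `a`: movement frames are
#'   multiplied by `1 + a/100` inside the class ROI, so a noiseless block
#'   scores `100 + a` there after mean-percent-signal-change collapsing.
#' @param noise_sd Standard deviation of the additive Gaussian noise per
#'   voxel per frame (scanner units), applied inside the brain mask only;
#'   the background stays exactly zero, as in masked real volumes.
#' @param roi_radius ROI sphere radius in voxels.
#' @param subject_effect_sd Log-scale sd of the per-subject baseline
#'   multiplier (`exp(rnorm(1, 0, sd))`).
#' @param baseline Peak baseline intensity inside the brain.
#' @param seed Generator seed; subjects are reproducible given
#'   `(seed, subject_index)`.
#' @return A `synth_config` object.
#' @export
synth_config <- function(dims = c(24L, 28L, 24L), frames_per_block = 12L,
                         amplitude_pct = 30, noise_sd = 1,
                         roi_radius = 3, subject_effect_sd = 0.1,
                         baseline = 1000, seed = 7L) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 8L), frames_per_block >= 1L)
  cfg <- structure(list(dims = dims,
                        frames_per_block = as.integer(frames_per_block),
                        amplitude_pct = amplitude_pct,
                        noise_sd = noise_sd,
                        roi_radius = roi_radius,
                        subject_effect_sd = subject_effect_sd,
                        baseline = baseline,
                        seed = as.integer(seed)),
                   class = "synth_config")
  cfg$baseline_map <- brain_baseline_map(dims, baseline)
  cfg$roi_masks <- roi_masks(dims, roi_radius)
  mask <- cfg$baseline_map > 0
  for (cl in MOVEMENT_CLASSES) {
    if (!all(mask[cfg$roi_masks[[cl]]])) {
      stop(new_error(paste0("ROI for class ", cl,
                            " falls outside the brain mask"),
                     "triplanar_roi_outside"))
    }
  }
  cfg
}

# Soft-edged ellipsoid: full intensity for normalized radius <= 0.85,
# linear falloff to zero at 1, exact zero outside.
brain_baseline_map <- function(dims, baseline) {
  ctr <- (dims + 1) / 2
  semi <- 0.45 * dims
  g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                   z = seq_len(dims[3L]))
  rho <- sqrt(((g$x - ctr[1L]) / semi[1L])^2 +
              ((g$y - ctr[2L]) / semi[2L])^2 +
              ((g$z - ctr[3L]) / semi[3L])^2)
  s <- pmin(1, pmax(0, (1 - rho) / 0.15))
  array(baseline * s, dims)
}

# Five fixed spherical ROIs at distinct fractional positions; spread in
# x, y and z so all three slicing planes separate the classes.
ROI_CENTRES <- list(LH = c(0.35, 0.38, 0.40),
                    RH = c(0.65, 0.38, 0.60),
                    LF = c(0.35, 0.62, 0.60),
                    RF = c(0.65, 0.62, 0.40),
                    T  = c(0.50, 0.50, 0.32))

roi_masks <- function(dims, radius) {
  g <- expand.grid(x = seq_len(dims[1L]), y = seq_len(dims[2L]),
                   z = seq_len(dims[3L]))
  out <- lapply(ROI_CENTRES, function(frac) {
    ctr <- 1 + frac * (dims - 1)
    d2 <- (g$x - ctr[1L])^2 + (g$y - ctr[2L])^2 + (g$z - ctr[3L])^2
    array(d2 <= radius^2, dims)
  })
  names(out) <- names(ROI_CENTRES)
  out
}

# The 13-block layout: fixation at the start, middle and end, with the 10
# movement blocks (2 per class, order shuffled per subject) in between.
motor_block_layout <- function(movement_order, frames_per_block) {
  labels <- c("FIXATION", movement_order[1:5], "FIXATION",
              movement_order[6:10], "FIXATION")
  data.frame(start_frame = (seq_along(labels) - 1L) * frames_per_block,
             n_frames = frames_per_block,
             label = labels)
}

#' Generate one synthetic subject
#'
#' Produces a 4D volume and its block schedule. Fixation frames are the
#' subject-scaled baseline plus noise; movement frames are additionally
#' multiplied by `1 + amplitude_pct/100` inside the block's class ROI.
#' Output is fully deterministic given `(cfg$seed, subject_index)`.
#'
#' @param cfg A `synth_config`.
#' @param subject_index 1-based subject index.
#' @return A list with `volume` (a `volume4d`) and `schedule`
#'   (a `block_schedule`).
#' @export
generate_subject <- function(cfg, subject_index) {
  stopifnot(inherits(cfg, "synth_config"), subject_index >= 1L)
  set.seed((cfg$seed * 10007L + as.integer(subject_index)) %% 2147483647L)
  mult <- exp(stats::rnorm(1L, 0, cfg$subject_effect_sd))
  movement_order <- sample(rep(MOVEMENT_CLASSES, 2L))
  layout <- motor_block_layout(movement_order, cfg$frames_per_block)
  T_total <- sum(layout$n_frames)
  schedule <- block_schedule(layout, T = T_total)
  base3d <- cfg$baseline_map * mult
  mask <- cfg$baseline_map > 0
  n_in <- sum(mask)
  dims <- cfg$dims
  data <- array(0, c(dims, T_total))
  for (b in seq_len(nrow(schedule))) {
    lab <- schedule$label[b]
    frame3d <- base3d
    if (lab != "FIXATION") {
      roi <- cfg$roi_masks[[lab]]
      frame3d[roi] <- frame3d[roi] * (1 + cfg$amplitude_pct / 100)
    }
    for (t in frames_of(schedule[b, ])) {
      f <- frame3d
      if (cfg$noise_sd > 0) {
        f[mask] <- f[mask] + stats::rnorm(n_in, 0, cfg$noise_sd)
      }
      data[, , , t] <- f
    }
  }
  list(volume = volume4d(data, subject_id = sprintf("sub%03d", subject_index)),
       schedule = schedule)
}

#' Generate a synthetic dataset
#'
#' @param cfg A `synth_config`.
#' @param n_subjects Number of subjects.
#' @return A list of per-subject lists (`volume`, `schedule`); each
#'   subject yields 10 labeled samples after [extract_samples()].
#' @export
generate_dataset <- function(cfg, n_subjects) {
  stopifnot(n_subjects >= 1L)
  lapply(seq_len(n_subjects), function(i) generate_subject(cfg, i))
}

#' Generate, preprocess and bundle a synthetic dataset
#'
#' Convenience wrapper: generates `n_subjects` subjects, collapses every
#' movement block with [extract_samples()], and bundles the results into
#' one `sample_set` (10 samples per subject, 2 per class).
#'
#' @inheritParams generate_dataset
#' @param convention Percent-signal-change convention; see [mean_psc()].
#' @return A `sample_set`.
#' @export
synth_sample_set <- function(cfg, n_subjects,
                             convention = c("ratio", "centered")) {
  convention <- match.arg(convention)
  subs <- generate_dataset(cfg, n_subjects)
  samples <- unlist(lapply(subs, function(s) {
    extract_samples(s$volume, s$schedule, convention = convention)
  }), recursive = FALSE)
  sample_set(samples)
}
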