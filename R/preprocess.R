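# Block-to-sample preprocessing: fixation baseline, mean percent signal
# change, and per-voxel normalization across samples.

frames_of <- function(block) {
  (block$start_frame + 1L):(block$start_frame + block$n_frames)
}

#' Per-voxel fixation baseline
#'
#' The baseline BOLD value of every voxel is the arithmetic mean of that
#' voxel over all frames of all fixation blocks, pooled.
#'
#' @param vol A `volume4d`.
#' @param schedule A `block_schedule` containing at least one fixation
#'   block.
#' @return A 3D array of baseline values with the volume's spatial shape.
#' @export
compute_baseline <- function(vol, schedule) {
  stopifnot(inherits(vol, "volume4d"))
  fix <- schedule[schedule$label == "FIXATION", , drop = FALSE]
  if (nrow(fix) == 0L) {
    stop(new_error("schedule has no fixation block; baseline undefined",
                   "triplanar_no_fixation"))
  }
  idx <- unlist(lapply(seq_len(nrow(fix)), function(i) frames_of(fix[i, ])))
  if (any(idx > dim(vol$data)[4L])) {
    stop(new_error("fixation block extends past the last frame",
                   "triplanar_block_overrun"))
  }
  rowMeans(vol$data[, , , idx, drop = FALSE], dims = 3L)
}

#' Mean percent signal change of one movement block
#'
#' Collapses the frames of one movement block to a single 3D image. For a
#' voxel with block values `y_1..y_N` and baseline `ybar`, the statistic is
#'
#'   `p = sum(y_i) / (ybar * N) * 100`
#'
#' i.e. the block mean expressed as a percentage of baseline: a block
#' identical to baseline scores 100 and an `a`% activation scores
#' `100 + a`. The `centered` convention subtracts 100 so that baseline
#' maps to 0 (the conventional percent-signal-change definition); the
#' default keeps the ratio form.
#'
#' Voxels whose baseline magnitude is below `eps` (e.g. masked background
#' outside the brain) are set to 0 and flagged in the `"baseline_masked"`
#' attribute of the result.
#'
#' @param vol A `volume4d`.
#' @param block One row of a `block_schedule` (a movement block).
#' @param ybar Baseline array from [compute_baseline()].
#' @param convention `"ratio"` (default, block mean / baseline * 100) or
#'   `"centered"` (subtract 100).
#' @param eps Baseline magnitude below which a voxel is masked out.
#' @return A 3D array; attribute `baseline_masked` is the logical mask of
#'   guarded voxels.
#' @export
mean_psc <- function(vol, block, ybar, convention = c("ratio", "centered"),
                     eps = 1e-8) {
  convention <- match.arg(convention)
  stopifnot(inherits(vol, "volume4d"))
  idx <- frames_of(block)
  N <- length(idx)
  ysum <- rowSums(vol$data[, , , idx, drop = FALSE], dims = 3L)
  masked <- abs(ybar) < eps
  denom <- ybar * N
  denom[masked] <- 1  # avoid 0/0; overwritten below
  p <- ysum / denom * 100
  if (convention == "centered") p <- p - 100
  p[masked] <- 0
  attr(p, "baseline_masked") <- masked
  p
}

#' Extract labeled 3D samples from a 4D volume
#'
#' Computes the fixation baseline, then collapses every movement block of
#' the schedule to one 3D image via [mean_psc()], labeled with the block's
#' movement class. Fixation blocks produce no samples; the motor-task
#' layout (3 fixation + 10 movement blocks) therefore yields exactly 10
#' samples per scan, 2 per class.
#'
#' @inheritParams mean_psc
#' @param schedule A `block_schedule`.
#' @return A list of `sample3d` objects, in block order.
#' @export
extract_samples <- function(vol, schedule, convention = c("ratio", "centered"),
                            eps = 1e-8) {
  convention <- match.arg(convention)
  mov <- schedule[schedule$label != "FIXATION", , drop = FALSE]
  if (nrow(mov) == 0L) return(list())
  ybar <- compute_baseline(vol, schedule)
  lapply(seq_len(nrow(mov)), function(i) {
    p <- mean_psc(vol, mov[i, ], ybar, convention = convention, eps = eps)
    attr(p, "baseline_masked") <- NULL
    sample3d(p, mov[i, "label"], vol$subject_id)
  })
}

#' Fit per-voxel normalization statistics
#'
#' Computes, for every voxel, the mean and the population (divide-by-n)
#' standard deviation across the given samples. The default reproduces the
#' all-samples behaviour (statistics pooled over the full dataset before
#' any split); fitting on training folds only and applying to test folds
#' gives the leakage-free variant — the `source` field records which was
#' done.
#'
#' @param set A `sample_set`.
#' @param source `"all_samples"` or `"train_only"` (a record, not a
#'   behaviour switch: pass the samples you want the statistics fit on).
#' @param eps Standard deviation below which a voxel is flagged as
#'   degenerate; such voxels are set to 0 by [apply_normalization()].
#' @return A `norm_stats` object: `mean`, `std` (3D arrays), `degenerate`
#'   (logical 3D array), `source`.
#' @export
fit_normalization <- function(set, source = c("all_samples", "train_only"),
                              eps = 1e-8) {
  source <- match.arg(source)
  stopifnot(inherits(set, "sample_set"), n_samples(set) >= 1L)
  m <- rowMeans(set$volumes, dims = 3L)
  v <- rowMeans(set$volumes^2, dims = 3L) - m^2
  s <- sqrt(pmax(v, 0))
  structure(list(mean = m, std = s, degenerate = s < eps, source = source),
            class = "norm_stats")
}

#' Apply per-voxel normalization
#'
#' Z-scores every voxel of every sample using fitted statistics; voxels
#' flagged degenerate (near-zero spread) are set to 0 after centering.
#'
#' @param set A `sample_set`.
#' @param stats A `norm_stats` from [fit_normalization()].
#' @return A `sample_set` of the same shape with normalized volumes.
#' @export
apply_normalization <- function(set, stats) {
  stopifnot(inherits(set, "sample_set"), inherits(stats, "norm_stats"))
  if (!identical(dim(stats$mean), set$dims)) {
    stop(new_error("normalization statistics shape does not match samples",
                   "triplanar_mixed_shapes"))
  }
  std <- stats$std
  std[stats$degenerate] <- 1
  out <- set
  n <- n_samples(set)
  for (i in seq_len(n)) {
    z <- (set$volumes[, , , i] - stats$mean) / std
    z[stats$degenerate] <- 0
    out$volumes[, , , i] <- z
  }
  out
}
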