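test_that("baseline is the pooled mean over all fixation frames", {
  tv <- tiny_volume_with_schedule(baseline = 7)
  expect_equal(compute_baseline(tv$vol, tv$schedule),
               array(7, c(4, 4, 4)))

  # a voxel with fixation values 2 and 4 averages to 3
  vol <- tv$vol
  fix1 <- 1L  # first frame of the first fixation block
  vol$data[1, 1, 1, ] <- 0
  fix_frames <- unlist(lapply(which(tv$schedule$label == "FIXATION"),
    function(b) triplanar:::frames_of(tv$schedule[b, ])))
  vol$data[1, 1, 1, fix_frames] <- rep(c(2, 4), length.out = length(fix_frames))
  expect_equal(compute_baseline(vol, tv$schedule)[1, 1, 1], 3)

  # single one-frame fixation block reproduces that frame
  sched1 <- block_schedule(data.frame(start_frame = c(0L, 1L),
                                      n_frames = c(1L, 3L),
                                      label = c("FIXATION", "LH")), T = 4L)
  arr <- array(rnorm(2 * 2 * 2 * 4), c(2, 2, 2, 4))
  expect_equal(compute_baseline(volume4d(arr), sched1), arr[, , , 1])

  no_fix <- block_schedule(data.frame(start_frame = 0L, n_frames = 4L,
                                      label = "LH"), T = 4L)
  expect_error(compute_baseline(volume4d(arr), no_fix),
               class = "triplanar_no_fixation")
})

test_that("mean percent signal change matches the printed formula", {
  # voxel values 2 then 4 over baseline 2: (2+4)/(2*2)*100 = 150
  arr <- array(0, c(2, 2, 2, 4))
  arr[, , , 1:2] <- 2          # fixation
  arr[, , , 3] <- 2
  arr[, , , 4] <- 4
  sched <- block_schedule(data.frame(start_frame = c(0L, 2L),
                                     n_frames = c(2L, 2L),
                                     label = c("FIXATION", "LH")), T = 4L)
  vol <- volume4d(arr)
  ybar <- compute_baseline(vol, sched)
  p <- mean_psc(vol, sched[2, ], ybar)
  expect_equal(as.vector(p), rep(150, 8))

  # block equal to baseline scores exactly 100
  arr2 <- array(5, c(2, 2, 2, 4))
  vol2 <- volume4d(arr2)
  ybar2 <- compute_baseline(vol2, sched)
  expect_equal(as.vector(mean_psc(vol2, sched[2, ], ybar2)), rep(100, 8))
  # centered convention maps baseline to 0
  expect_equal(as.vector(mean_psc(vol2, sched[2, ], ybar2,
                                  convention = "centered")), rep(0, 8))

  # zero numerator gives 0
  arr3 <- arr2
  arr3[, , , 3:4] <- 0
  vol3 <- volume4d(arr3)
  expect_equal(as.vector(mean_psc(vol3, sched[2, ], compute_baseline(vol3, sched))),
               rep(0, 8))
})

test_that("near-zero baselines are guarded and flagged", {
  arr <- array(5, c(2, 2, 2, 4))
  arr[1, 1, 1, 1:2] <- 0  # background voxel: baseline 0
  sched <- block_schedule(data.frame(start_frame = c(0L, 2L),
                                     n_frames = c(2L, 2L),
                                     label = c("FIXATION", "LH")), T = 4L)
  vol <- volume4d(arr)
  p <- mean_psc(vol, sched[2, ], compute_baseline(vol, sched))
  expect_equal(p[1, 1, 1], 0)
  expect_true(attr(p, "baseline_masked")[1, 1, 1])
  expect_equal(sum(attr(p, "baseline_masked")), 1L)
})

test_that("mean PSC is invariant to joint rescaling of block and baseline", {
  set.seed(5)
  arr <- array(runif(2 * 2 * 2 * 6, 1, 10), c(2, 2, 2, 6))
  sched <- block_schedule(data.frame(start_frame = c(0L, 3L),
                                     n_frames = c(3L, 3L),
                                     label = c("FIXATION", "RH")), T = 6L)
  for (s in c(0.1, 3, 1000)) {
    v1 <- volume4d(arr)
    v2 <- volume4d(arr * s)
    p1 <- mean_psc(v1, sched[2, ], compute_baseline(v1, sched))
    p2 <- mean_psc(v2, sched[2, ], compute_baseline(v2, sched))
    expect_equal(as.vector(p1), as.vector(p2), tolerance = 1e-12)
  }
})

test_that("extract_samples yields one labeled sample per movement block", {
  tv <- tiny_volume_with_schedule()
  samples <- extract_samples(tv$vol, tv$schedule)
  mov <- tv$labels[tv$labels != "FIXATION"]
  expect_length(samples, length(mov))
  expect_identical(vapply(samples, `[[`, character(1), "label"), mov)
  expect_true(all(vapply(samples, `[[`, character(1), "subject_id") == "t01"))

  fix_only <- block_schedule(data.frame(start_frame = 0L, n_frames = 4L,
                                        label = "FIXATION"), T = 16L)
  expect_identical(extract_samples(tv$vol, fix_only), list())
})

test_that("the 13-block motor layout yields 10 samples, 2 per class", {
  cfg <- fast_synth_config(noise_sd = 0, subject_effect_sd = 0)
  sub <- generate_subject(cfg, 1L)
  samples <- extract_samples(sub$volume, sub$schedule)
  expect_length(samples, 10L)
  labs <- vapply(samples, `[[`, character(1), "label")
  expect_equal(as.integer(table(labs)[MOVEMENT_CLASSES]), rep(2L, 5L))
})

test_that("per-voxel normalization z-scores across samples", {
  # two samples with voxel values 1 and 3: population sd 1, z-scores -1, +1
  s <- list(sample3d(array(1, c(2, 2, 2)), "LH", "a"),
            sample3d(array(3, c(2, 2, 2)), "RH", "a"))
  set <- sample_set(s)
  st <- fit_normalization(set)
  out <- apply_normalization(set, st)
  expect_equal(as.vector(out$volumes[, , , 1]), rep(-1, 8))
  expect_equal(as.vector(out$volumes[, , , 2]), rep(1, 8))

  # single sample: centered to zero under the degenerate-sd guard
  one <- sample_set(s[1])
  out1 <- apply_normalization(one, fit_normalization(one))
  expect_equal(as.vector(out1$volumes), rep(0, 8))

  # applying to already standardized data returns it unchanged
  st2 <- st
  st2$mean[] <- 0
  st2$std[] <- 1
  st2$degenerate[] <- FALSE
  again <- apply_normalization(out, st2)
  expect_equal(again$volumes, out$volumes)
})

test_that("fit+apply leaves every voxel with mean ~0 and population sd ~1", {
  set <- tiny_sample_set(dims = c(5L, 6L, 5L), n_subjects = 3L,
                         per_subject = 4L, seed = 11)
  out <- apply_normalization(set, fit_normalization(set))
  m <- rowMeans(out$volumes, dims = 3)
  v <- rowMeans(out$volumes^2, dims = 3) - m^2
  expect_lt(max(abs(m)), 1e-6)
  expect_lt(max(abs(sqrt(v) - 1)), 1e-6)
})

test_that("normalization statistics must match the sample shape", {
  set <- tiny_sample_set()
  st <- fit_normalization(tiny_sample_set(dims = c(6L, 6L, 6L)))
  expect_error(apply_normalization(set, st), class = "triplanar_mixed_shapes")
})
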