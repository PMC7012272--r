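# In-code fixtures shared across test files.

# A sample_set of random volumes with cycling labels and grouped subjects.
tiny_sample_set <- function(dims = c(12L, 14L, 12L), n_subjects = 2L,
                            per_subject = 5L, seed = 1L) {
  set.seed(seed)
  n <- n_subjects * per_subject
  samples <- lapply(seq_len(n), function(i) {
    sample3d(array(rnorm(prod(dims)), dims),
             MOVEMENT_CLASSES[((i - 1L) %% 5L) + 1L],
             sprintf("s%02d", ((i - 1L) %/% per_subject) + 1L))
  })
  sample_set(samples)
}

# A small 4D volume + motor-style schedule built by hand.
tiny_volume_with_schedule <- function(dims = c(4L, 4L, 4L), fpb = 2L,
                                      baseline = 10, seed = 1L) {
  set.seed(seed)
  labels <- c("FIXATION", "LH", "RH", "FIXATION", "LF", "RF", "T", "FIXATION")
  T_total <- length(labels) * fpb
  data <- array(baseline, c(dims, T_total))
  sched <- block_schedule(data.frame(
    start_frame = (seq_along(labels) - 1L) * fpb,
    n_frames = fpb, label = labels), T = T_total)
  list(vol = volume4d(data, subject_id = "t01"), schedule = sched,
       labels = labels, fpb = fpb)
}

# A fast low-resolution synthetic configuration for pipeline tests.
fast_synth_config <- function(...) {
  synth_config(dims = c(12L, 14L, 12L), frames_per_block = 4L,
               roi_radius = 2, ...)
}
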