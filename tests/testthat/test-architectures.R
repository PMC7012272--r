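test_that("conv stack unit arithmetic follows the shrink-then-floor recurrence", {
  expect_equal(conv_stack_units(c(91, 109)), 16800L)
  expect_equal(conv_stack_units(c(91, 109, 91)), 352800L)
  expect_equal(conv_stack_units(9919L), 79296L)
  # 21 -> 19 -> 9 -> 7 -> 3 per dim, times 32 channels
  expect_equal(conv_stack_units(c(21, 21)), 288L)
  expect_error(conv_stack_units(c(9, 9)), "collapsed")
})

PUBLISHED_TOTALS <- c(mv2d = 2223877, s2d = 2236837, conv1d = 10474501,
                      conv3d = 45174181, conv3d_sep = 45161301, m2d = 6355717)
PUBLISHED_UNITS <- c(mv2d = 16800, s2d = 16800, conv1d = 79296,
                     conv3d = 352800, conv3d_sep = 352800, m2d = 47712)

test_that("closed-form totals reproduce the reference configuration exactly", {
  for (kind in names(PUBLISHED_TOTALS)) {
    cf <- count_parameters_closed_form(arch_config(kind))
    expect_identical(cf$total_parameters, PUBLISHED_TOTALS[[kind]],
                     label = paste(kind, "total"))
    expect_identical(cf$flatten_units, PUBLISHED_UNITS[[kind]],
                     label = paste(kind, "units"))
    expect_identical(sum(cf$per_layer$count), cf$total_parameters)
  }
})

test_that("structural differences between families have closed-form sizes", {
  cf <- function(kind) count_parameters_closed_form(arch_config(kind))$total_parameters
  # s2d and mv2d differ only in conv1 input channels: 3*3*(91-1)*16
  expect_equal(cf("s2d") - cf("mv2d"), 3L * 3L * 90L * 16L)
  # factorizing layer 2 saves 27*16*32+32 - (27*16 + 16*32+32) parameters
  expect_equal(cf("conv3d") - cf("conv3d_sep"), 12880L)
})

test_that("disabling normalization removes exactly the 4-per-feature terms", {
  config <- arch_config("mv2d")
  full <- count_parameters_closed_form(config)
  config$norm_after_pool <- FALSE
  config$norm_after_merge <- FALSE
  config$norm_after_dense <- FALSE
  bare <- count_parameters_closed_form(config)
  norm_terms <- 4L * (16L + 32L + 16800L + 128L)
  expect_equal(full$total_parameters - bare$total_parameters, norm_terms)
})

test_that("built models and the closed form agree for every family (small input)", {
  set.seed(1)
  for (kind in names(PUBLISHED_TOTALS)) {
    v <- verify_counts(arch_config(kind, input_dim = c(12L, 14L, 12L)))
    expect_true(v$ok, label = paste(kind, "count verification"))
    expect_equal(v$closed_form$total_parameters, v$built$total_parameters)
  }
})

test_that("built models and the closed form agree for random configurations", {
  set.seed(20)
  for (rep in 1:20) {
    kind <- sample(c("m2d", "s2d", "mv2d", "conv1d", "conv3d", "conv3d_sep"), 1)
    dims <- sample(11:18, 3, replace = TRUE)
    ch <- sort(sample(2:12, 2))
    ncls <- sample(2:6, 1)
    dense <- sample(c(8L, 16L, 32L), 1)
    cfg <- arch_config(kind, input_dim = dims, conv_channels = ch,
                       n_classes = ncls, dense_units = dense)
    v <- verify_counts(cfg)
    expect_true(v$ok, label = sprintf("%s dims=%s ch=%s ncls=%d dense=%d",
                                      kind, paste(dims, collapse = "x"),
                                      paste(ch, collapse = "/"), ncls, dense))
  }
})

test_that("forward passes land on the probability simplex", {
  set.seed(4)
  dims <- c(12L, 14L, 12L)
  set <- tiny_sample_set(dims = dims, n_subjects = 1L, per_subject = 3L)
  for (kind in names(PUBLISHED_TOTALS)) {
    model <- build_model(arch_config(kind, input_dim = dims))
    probs <- predict_proba(model, prepare_inputs(set, kind))
    expect_identical(dim(probs), c(3L, 5L))
    expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
    expect_true(all(probs > 0 & probs < 1))
  }
})

unclass_arch_test <- function(x) {
  attr(x, "axis") <- NULL
  class(x) <- NULL
  x
}

test_that("prepare_inputs produces the representation each family expects", {
  dims <- c(6L, 7L, 8L)
  set <- tiny_sample_set(dims = dims, n_subjects = 1L, per_subject = 2L)
  x <- prepare_inputs(set, "m2d")
  expect_length(x, 3L)
  expect_identical(dim(x[[1]]), c(7L, 8L, 6L, 2L))
  expect_identical(dim(x[[2]]), c(6L, 8L, 7L, 2L))
  expect_identical(dim(x[[3]]), c(6L, 7L, 8L, 2L))
  # branch batches agree with the per-sample slicing transforms
  tp <- to_triplanar(set$volumes[, , , 1])
  expect_equal(x[[1]][, , , 1], unclass_arch_test(tp$x))
  expect_equal(x[[2]][, , , 1], unclass_arch_test(tp$y))
  expect_identical(dim(prepare_inputs(set, "s2d")[[1]]), c(6L, 7L, 8L, 2L))
  mv <- prepare_inputs(set, "mv2d")[[1]]
  expect_identical(dim(mv), c(6L, 7L, 1L, 2L))
  expect_equal(mv[, , 1, 2], to_mean_value_2d(set$volumes[, , , 2]))
  sq <- prepare_inputs(set, "conv1d")[[1]]
  expect_identical(dim(sq), c(56L, 6L, 2L))
  expect_equal(sq[, , 1], to_sequence_1d(set$volumes[, , , 1]))
  expect_identical(dim(prepare_inputs(set, "conv3d")[[1]]), c(6L, 7L, 8L, 1L, 2L))
})

test_that("branch count mismatches are rejected at the model boundary", {
  model <- build_model(arch_config("m2d", input_dim = c(12L, 14L, 12L)))
  expect_error(predict_proba(model, list(array(0, c(14, 12, 12, 1)))),
               class = "triplanar_bad_input")
})
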