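test_that("subject-wise splits are disjoint, covering, and deterministic", {
  ids <- rep(sprintf("s%02d", 1:10), each = 10)
  folds <- split_subjectwise(ids, k = 5, seed = 3)
  expect_length(folds, 5L)
  all_test <- unlist(lapply(folds, `[[`, "test_subjects"))
  expect_setequal(all_test, unique(ids))
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(f$test_subjects, 2L)
    expect_length(intersect(f$train_subjects, f$test_subjects), 0L)
    expect_length(intersect(f$train_subjects, f$val_subjects), 0L)
    expect_length(intersect(f$val_subjects, f$test_subjects), 0L)
    expect_setequal(c(f$train_subjects, f$val_subjects, f$test_subjects),
                    unique(ids))
  }
  expect_identical(folds, split_subjectwise(ids, k = 5, seed = 3))
  expect_false(identical(folds, split_subjectwise(ids, k = 5, seed = 4)))
})

test_that("a 995-subject cohort splits into 5 test sets of 199", {
  ids <- sprintf("s%04d", 1:995)
  folds <- split_subjectwise(ids, k = 5, seed = 1)
  expect_equal(vapply(folds, function(f) length(f$test_subjects), integer(1)),
               rep(199L, 5))
  # validation is ~10% of the remaining 796 subjects
  expect_equal(vapply(folds, function(f) length(f$val_subjects), integer(1)),
               rep(80L, 5))
  expect_error(split_subjectwise(c("a", "b"), k = 5),
               class = "triplanar_too_few_subjects")
})

test_that("the learning rate halves every 50 epochs from 0.0025", {
  expect_equal(lr_at_epoch(0), 0.0025)
  expect_equal(lr_at_epoch(49), 0.0025)
  expect_equal(lr_at_epoch(50), 0.00125)
  expect_equal(lr_at_epoch(99), 0.00125)
  expect_equal(lr_at_epoch(100), 0.000625)
  expect_equal(lr_at_epoch(0:300), 0.0025 * 0.5^(0:300 %/% 50))
})

test_that("train-loss patience stops stalled streams and spares improving ones", {
  es <- triplanar:::early_stop_epoch
  # constant stream: first epoch sets the floor, then 6 stalled epochs
  expect_equal(es(rep(1, 20), patience = 6), 7L)
  expect_true(is.na(es(seq(2, 0.1, length.out = 50), patience = 6)))
  # plateau after improvement
  expect_equal(es(c(3, 2, 1, 1, 1, 1, 1, 1, 1), patience = 6), 9L)
  # a late dip resets the counter
  expect_true(is.na(es(c(3, 1, 1, 1, 1, 1, 0.5), patience = 6)))
})

test_that("training with a zero learning rate early-stops after the patience window", {
  set.seed(8)
  dims <- c(12L, 14L, 12L)
  # identical samples, dropout off, zero learning rate: the per-epoch loss
  # is bit-identical regardless of shuffling, i.e. an exactly constant stream
  v <- array(rnorm(prod(dims)), dims)
  set <- sample_set(lapply(1:8, function(i) sample3d(v, "LH", "s1")))
  model <- build_model(arch_config("mv2d", input_dim = dims, dropout = 0))
  fit <- train(model, prepare_inputs(set, "mv2d"), set$labels,
               prepare_inputs(set, "mv2d"), set$labels,
               max_epochs = 30, lr_base = 0, batch_size = n_samples(set),
               seed = 1)
  # parameters never move, so the loss is constant: epochs 0..6 run (1 floor
  # + 6 without improvement), then training stops
  expect_equal(fit$stopped_epoch, 6L)
  expect_equal(nrow(fit$history), 7L)
})

test_that("the checkpointed model reproduces the best recorded validation accuracy", {
  set.seed(15)
  dims <- c(12L, 14L, 12L)
  tr <- tiny_sample_set(dims = dims, n_subjects = 3L, per_subject = 5L, seed = 2)
  va <- tiny_sample_set(dims = dims, n_subjects = 1L, per_subject = 5L, seed = 3)
  model <- build_model(arch_config("mv2d", input_dim = dims))
  fit <- train(model, prepare_inputs(tr, "mv2d"), tr$labels,
               prepare_inputs(va, "mv2d"), va$labels,
               max_epochs = 5, seed = 4)
  best <- max(fit$history$val_accuracy)
  expect_equal(fit$history$val_accuracy[fit$best_epoch + 1L], best)
  r <- evaluate(fit$model, prepare_inputs(va, "mv2d"), va$labels)
  expect_equal(r$accuracy, best)
})

test_that("classification metrics match hand-computed confusion matrices", {
  perfect <- classification_metrics(MOVEMENT_CLASSES, MOVEMENT_CLASSES)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$f1, 1)
  # with only a subset of classes observed, the absent classes contribute
  # precision/F1 zero to the macro average over the full class set
  partial <- classification_metrics(c("LH", "RH", "LF"), c("LH", "RH", "LF"))
  expect_equal(partial$accuracy, 1)
  expect_equal(partial$precision, 3 / 5)

  # confusion [[3,1],[1,3]] on a two-class reduction
  truth <- c(rep("A", 4), rep("B", 4))
  pred <- c("A", "A", "A", "B", "B", "B", "B", "A")
  m <- classification_metrics(truth, pred, classes = c("A", "B"))
  expect_equal(unname(m$confusion), rbind(c(3, 1), c(1, 3)))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(unname(rowSums(m$confusion)), c(4, 4))

  # a never-predicted class contributes precision 0 to the macro average
  m2 <- classification_metrics(c("A", "B"), c("A", "A"), classes = c("A", "B"))
  expect_equal(m2$precision, mean(c(0.5, 0)))
})

test_that("the PCA+SVM baseline separates linearly separable classes", {
  set.seed(6)
  n_per <- 10L
  centers <- diag(5) * 8
  x <- do.call(rbind, lapply(1:5, function(k) {
    matrix(rnorm(n_per * 20), n_per, 20) +
      matrix(rep(c(centers[k, ], numeric(15)), each = n_per), n_per, 20)
  }))
  y <- rep(MOVEMENT_CLASSES, each = n_per)
  r <- pca_svm_baseline(x, y, x, y, n_components = 10)
  expect_equal(r$accuracy, 1)
  # requesting more components than available clamps with a warning
  expect_warning(r2 <- pca_svm_baseline(x, y, x, y, n_components = 500),
                 "reduced")
  expect_gte(r2$accuracy, 0.2)
})

test_that("cross-validation runs end to end and is reproducible", {
  cfg <- fast_synth_config(seed = 11L)
  set <- synth_sample_set(cfg, n_subjects = 6L)
  cv <- crossval(set, "mv2d", k = 5, seed = 2, max_epochs = 2)
  expect_length(cv$folds, 5L)
  expect_true(all(is.finite(cv$summary$mean)))
  expect_true(all(is.finite(cv$summary$sd)))
  cv2 <- crossval(set, "mv2d", k = 5, seed = 2, max_epochs = 2)
  expect_identical(cv$splits, cv2$splits)
  expect_equal(cv$summary, cv2$summary)
})

test_that("train-only normalization keeps test data out of the training path", {
  cfg <- fast_synth_config(seed = 12L)
  set <- synth_sample_set(cfg, n_subjects = 5L)
  subjects <- unique(set$subject_ids)
  te_idx <- which(set$subject_ids == subjects[1])
  tr_idx <- which(set$subject_ids %in% subjects[2:4])
  va_idx <- which(set$subject_ids == subjects[5])
  run <- function(s) {
    set.seed(42)  # pin weight initialisation alongside train()'s own seed
    st <- fit_normalization(subset_samples(s, tr_idx), source = "train_only")
    sn <- apply_normalization(s, st)
    model <- build_model(arch_config("mv2d", input_dim = s$dims))
    train(model, prepare_inputs(subset_samples(sn, tr_idx), "mv2d"),
          sn$labels[tr_idx],
          prepare_inputs(subset_samples(sn, va_idx), "mv2d"),
          sn$labels[va_idx], max_epochs = 2, seed = 99)$history
  }
  h1 <- run(set)
  perturbed <- set
  perturbed$volumes[, , , te_idx] <- perturbed$volumes[, , , te_idx] + 50
  h2 <- run(perturbed)
  expect_identical(h1, h2)
})
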