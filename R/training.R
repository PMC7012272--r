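# Subject-wise cross-validation, the training loop (Adam, stepped learning
# rate, train-loss early stopping, best-validation checkpointing), metrics,
# and the PCA+SVM baseline.

#' Subject-wise k-fold split
#'
#' Partitions subjects (not samples) into k folds so that every sample of
#' a subject lands on the same side of every split. Per fold, roughly 1/k
#' of the subjects are the test set; of the remaining subjects, 10% are
#' held out as validation and the rest are the training set. Deterministic
#' given `seed`.
#'
#' @param subject_ids Character vector of subject identifiers (duplicates
#'   allowed; unique values are split).
#' @param k Number of folds.
#' @param seed Integer seed controlling the shuffle.
#' @param val_fraction Fraction of non-test subjects held out for
#'   validation.
#' @return A list of `k` fold splits, each a list with `fold_id` (0-based)
#'   and disjoint character vectors `train_subjects`, `val_subjects`,
#'   `test_subjects`.
#' @export
split_subjectwise <- function(subject_ids, k = 5L, seed = 1L,
                              val_fraction = 0.1) {
  subs <- unique(as.character(subject_ids))
  if (length(subs) < k) {
    stop(new_error(paste0("need at least k = ", k, " subjects, got ",
                          length(subs)), "triplanar_too_few_subjects"))
  }
  set.seed(as.integer(seed))
  subs <- sample(subs)
  fold_of <- rep(seq_len(k), length.out = length(subs))
  lapply(seq_len(k), function(i) {
    test <- subs[fold_of == i]
    rest <- subs[fold_of != i]
    n_val <- max(1L, round(val_fraction * length(rest)))
    val <- rest[seq_len(n_val)]
    train <- rest[-seq_len(n_val)]
    list(fold_id = i - 1L, train_subjects = train, val_subjects = val,
         test_subjects = test)
  })
}

#' Stepped learning-rate schedule
#'
#' The learning rate starts at `base` and is halved every `every` epochs:
#' `base * drop^(epoch %/% every)` with 0-based epochs.
#'
#' @param epoch 0-based epoch index.
#' @param base Initial learning rate.
#' @param drop Multiplicative factor applied at each step.
#' @param every Epochs between steps.
#' @return The learning rate for that epoch.
#' @examples
#' lr_at_epoch(0)    # 0.0025
#' lr_at_epoch(100)  # 0.000625
#' @export
lr_at_epoch <- function(epoch, base = 0.0025, drop = 0.5, every = 50L) {
  stopifnot(all(epoch >= 0))
  base * drop^(epoch %/% every)
}

# Epoch (1-based) at which training stops for a given train-loss stream:
# stop once the running minimum has not strictly decreased for `patience`
# consecutive epochs. NA if the stream never triggers the rule.
early_stop_epoch <- function(losses, patience = 6L) {
  best <- Inf
  stalled <- 0L
  for (i in seq_along(losses)) {
    if (losses[i] < best) {
      best <- losses[i]
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) return(i)
    }
  }
  NA_integer_
}

cross_entropy <- function(probs, y_index) {
  p <- probs[cbind(seq_len(nrow(probs)), y_index)]
  -mean(log(pmax(p, 1e-12)))
}

slice_inputs <- function(inputs, idx) {
  lapply(inputs, function(a) {
    nd <- length(dim(a))
    if (nd == 3L) a[, , idx, drop = FALSE]
    else if (nd == 4L) a[, , , idx, drop = FALSE]
    else a[, , , , idx, drop = FALSE]
  })
}

snapshot_params <- function(layers) {
  lapply(layers, function(l) list(params = l$params, buffers = l$buffers))
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    layers[[i]]$buffers <- snap[[i]]$buffers
  }
  invisible(NULL)
}

#' Train a model
#'
#' Minimises categorical cross-entropy with Adam under the stepped
#' learning-rate schedule of [lr_at_epoch()]. After every epoch the model
#' is evaluated on the validation set and the epoch with the best
#' validation result is checkpointed (by default best validation
#' accuracy, ties to the earliest epoch; `select = "loss"` switches to
#' lowest validation loss). Training stops when the training loss has not
#' decreased below its running minimum for `patience` consecutive epochs,
#' or after `max_epochs`. The returned model carries the checkpointed
#' weights.
#'
#' @param model A `tp_model` from [build_model()].
#' @param train_inputs,train_labels Batched training inputs
#'   ([prepare_inputs()]) and a factor/character label vector.
#' @param val_inputs,val_labels Validation inputs and labels.
#' @param max_epochs Hard cap on epochs.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience on the training loss.
#' @param lr_base,lr_drop,lr_every Learning-rate schedule parameters.
#' @param select Validation selection criterion, `"accuracy"` or
#'   `"loss"`.
#' @param classes Class levels; defaults to `MOVEMENT_CLASSES`.
#' @param seed Optional integer seed for shuffling, weight use and
#'   dropout within this call.
#' @param verbose Print per-epoch progress.
#' @return A list: `model` (checkpointed), `history` (data frame with
#'   epoch, lr, train_loss, val_loss, val_accuracy), `best_epoch`
#'   (0-based), `stopped_epoch` (0-based, NA if the cap was hit).
#' @export
train <- function(model, train_inputs, train_labels,
                  val_inputs, val_labels,
                  max_epochs = 100L, batch_size = 32L, patience = 6L,
                  lr_base = 0.0025, lr_drop = 0.5, lr_every = 50L,
                  select = c("accuracy", "loss"),
                  classes = MOVEMENT_CLASSES, seed = NULL,
                  verbose = FALSE) {
  select <- match.arg(select)
  if (!is.null(seed)) set.seed(as.integer(seed))
  y_train <- match(as.character(train_labels), classes)
  y_val <- match(as.character(val_labels), classes)
  if (anyNA(y_train) || anyNA(y_val)) stop("labels outside the class set")
  n <- length(y_train)
  stopifnot(n >= 1L, length(y_val) >= 1L)
  layers <- model_layers(model)
  adam_init(layers)
  ncls <- model$config$n_classes
  onehot <- diag(ncls)
  best_metric <- -Inf
  best_epoch <- NA_integer_
  best_snap <- snapshot_params(layers)
  best_train_loss <- Inf
  stalled <- 0L
  stopped <- NA_integer_
  hist <- list()
  step <- 0L
  for (epoch in seq_len(max_epochs) - 1L) {
    lr <- lr_at_epoch(epoch, lr_base, lr_drop, lr_every)
    ord <- sample.int(n)
    batch_losses <- numeric(0)
    for (b in seq_len(ceiling(n / batch_size))) {
      idx <- ord[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      xb <- slice_inputs(train_inputs, idx)
      yb <- y_train[idx]
      probs <- model_forward(model, xb, training = TRUE)
      if (!all(is.finite(probs))) {
        stop(new_error("non-finite output during training (diverged?)",
                       "triplanar_nonfinite"))
      }
      loss <- cross_entropy(probs, yb)
      batch_losses <- c(batch_losses, loss)
      dlogits <- (probs - onehot[yb, , drop = FALSE]) / length(idx)
      model_backward(model, dlogits)
      step <- step + 1L
      adam_step(layers, lr, step)
    }
    clear_caches(layers)
    train_loss <- mean(batch_losses)
    vp <- model_forward(model, val_inputs, training = FALSE)
    val_loss <- cross_entropy(vp, y_val)
    val_acc <- mean(max.col(vp, ties.method = "first") == y_val)
    hist[[epoch + 1L]] <- data.frame(epoch = epoch, lr = lr,
                                     train_loss = train_loss,
                                     val_loss = val_loss,
                                     val_accuracy = val_acc)
    metric <- if (select == "accuracy") val_acc else -val_loss
    if (metric > best_metric) {
      best_metric <- metric
      best_epoch <- epoch
      best_snap <- snapshot_params(layers)
    }
    if (verbose) {
      message(sprintf("epoch %3d lr %.5f train %.4f val %.4f acc %.3f",
                      epoch, lr, train_loss, val_loss, val_acc))
    }
    if (train_loss < best_train_loss) {
      best_train_loss <- train_loss
      stalled <- 0L
    } else {
      stalled <- stalled + 1L
      if (stalled >= patience) {
        stopped <- epoch
        break
      }
    }
  }
  restore_params(layers, best_snap)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, stopped_epoch = stopped)
}

#' Classification metrics from labels and predictions
#'
#' Accuracy, macro-averaged precision and macro-averaged F1 over a fixed
#' class set, plus the confusion matrix (rows: truth, columns:
#' prediction). A class never predicted contributes precision 0; a class
#' with no predictions and no true positives contributes F1 0.
#'
#' @param truth,pred Character/factor vectors over `classes`.
#' @param classes Class levels defining the confusion matrix order.
#' @return A `metrics_report`: `accuracy`, `precision`, `f1`, `confusion`,
#'   `per_class` (data frame).
#' @export
classification_metrics <- function(truth, pred, classes = MOVEMENT_CLASSES) {
  truth <- factor(as.character(truth), levels = classes)
  pred <- factor(as.character(pred), levels = classes)
  stopifnot(!anyNA(truth), !anyNA(pred), length(truth) == length(pred))
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  pred_n <- colSums(cm)
  true_n <- rowSums(cm)
  prec <- ifelse(pred_n > 0, tp / pred_n, 0)
  rec <- ifelse(true_n > 0, tp / true_n, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  structure(list(accuracy = sum(tp) / length(truth),
                 precision = mean(prec),
                 f1 = mean(f1),
                 confusion = unclass(cm),
                 per_class = data.frame(class = classes, precision = prec,
                                        recall = rec, f1 = f1,
                                        row.names = NULL)),
            class = "metrics_report")
}

#' Evaluate a trained model on a test set
#'
#' @param model A trained `tp_model`.
#' @param test_inputs Batched inputs ([prepare_inputs()]).
#' @param test_labels True labels.
#' @param classes Class levels.
#' @return A `metrics_report`; see [classification_metrics()].
#' @export
evaluate <- function(model, test_inputs, test_labels,
                     classes = MOVEMENT_CLASSES) {
  if (length(test_labels) == 0L) {
    stop(new_error("empty test set", "triplanar_empty_test"))
  }
  probs <- predict_proba(model, test_inputs)
  pred <- classes[max.col(probs, ties.method = "first")]
  classification_metrics(test_labels, pred, classes)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  macro precision %.4f  macro F1 %.4f\n",
              x$accuracy, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' PCA + linear SVM baseline
#'
#' Flattened voxel vectors are projected onto the top principal
#' directions fit on the training set (500 components by default, clamped
#' with a warning when fewer are available) and classified with a linear
#' support vector machine (`C = 1`).
#'
#' @param train_x,test_x Numeric matrices (samples in rows) of flattened
#'   volumes, e.g. built with [flatten_for_svm()].
#' @param train_y,test_y Label vectors.
#' @param n_components Number of principal components retained.
#' @param C SVM cost parameter.
#' @param classes Class levels.
#' @return A `metrics_report` on the test set.
#' @export
pca_svm_baseline <- function(train_x, train_y, test_x, test_y,
                             n_components = 500L, C = 1.0,
                             classes = MOVEMENT_CLASSES) {
  stopifnot(is.matrix(train_x), is.matrix(test_x),
            ncol(train_x) == ncol(test_x))
  max_comp <- min(nrow(train_x) - 1L, ncol(train_x))
  if (n_components > max_comp) {
    warning("n_components reduced from ", n_components, " to ", max_comp)
    n_components <- max_comp
  }
  pc <- stats::prcomp(train_x, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  ztr <- pc$x
  zte <- scale(test_x, center = pc$center, scale = FALSE) %*% pc$rotation
  fit <- e1071::svm(x = ztr, y = factor(as.character(train_y), levels = classes),
                    kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  pred <- as.character(stats::predict(fit, zte))
  classification_metrics(test_y, pred, classes)
}

#' Subject-wise cross-validated training and evaluation
#'
#' Runs the full harness for one model family: subject-wise k-fold split,
#' per-fold normalization (all-samples statistics by default, or fit on
#' the training fold only), training with checkpointing and early
#' stopping, and test-set evaluation. `model_kind = "pca_svm"` runs the
#' PCA+SVM baseline instead of a network.
#'
#' @param set A `sample_set` with subject ids.
#' @param model_kind One of `MODEL_KINDS` or `"pca_svm"`.
#' @param k Number of folds.
#' @param seed Run seed; controls the split and, per fold, weight
#'   initialisation, shuffling and dropout.
#' @param norm `"all_samples"` (statistics over the full dataset) or
#'   `"train_only"` (statistics from the training fold, applied to all
#'   partitions).
#' @param n_components,C PCA+SVM baseline settings.
#' @param ... Further arguments passed to [train()] (e.g. `max_epochs`,
#'   `batch_size`).
#' @return A `crossval_result`: `folds` (list of `metrics_report`s),
#'   `summary` (data frame of mean and sd for accuracy, precision, f1),
#'   `histories`, `splits`.
#' @export
crossval <- function(set, model_kind, k = 5L, seed = 1L,
                     norm = c("all_samples", "train_only"),
                     n_components = 500L, C = 1.0, ...) {
  norm <- match.arg(norm)
  kinds <- c(MODEL_KINDS, "pca_svm")
  model_kind <- match.arg(model_kind, kinds)
  splits <- split_subjectwise(set$subject_ids, k = k, seed = seed)
  all_stats <- if (norm == "all_samples") fit_normalization(set) else NULL
  reports <- vector("list", k)
  histories <- vector("list", k)
  for (f in seq_len(k)) {
    sp <- splits[[f]]
    tr_idx <- which(set$subject_ids %in% sp$train_subjects)
    va_idx <- which(set$subject_ids %in% sp$val_subjects)
    te_idx <- which(set$subject_ids %in% sp$test_subjects)
    stats <- if (norm == "all_samples") all_stats else
      fit_normalization(subset_samples(set, tr_idx), source = "train_only")
    norm_set <- apply_normalization(set, stats)
    tr <- subset_samples(norm_set, tr_idx)
    va <- subset_samples(norm_set, va_idx)
    te <- subset_samples(norm_set, te_idx)
    if (model_kind == "pca_svm") {
      flat <- function(s) t(matrix(s$volumes, prod(s$dims), n_samples(s)))
      reports[[f]] <- pca_svm_baseline(flat(tr), tr$labels, flat(te), te$labels,
                                       n_components = n_components, C = C)
    } else {
      config <- arch_config(model_kind, input_dim = set$dims)
      model <- build_model(config)
      fit <- train(model,
                   prepare_inputs(tr, model_kind), tr$labels,
                   prepare_inputs(va, model_kind), va$labels,
                   seed = seed + 1000L * f, ...)
      reports[[f]] <- evaluate(fit$model, prepare_inputs(te, model_kind),
                               te$labels)
      histories[[f]] <- fit$history
    }
  }
  metric_mat <- vapply(reports, function(r) c(r$accuracy, r$precision, r$f1),
                       numeric(3))
  summary <- data.frame(metric = c("accuracy", "precision", "f1"),
                        mean = rowMeans(metric_mat),
                        sd = apply(metric_mat, 1L, stats::sd))
  structure(list(model_kind = model_kind, folds = reports, summary = summary,
                 histories = histories, splits = splits, seed = seed,
                 norm = norm),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(x$model_kind, "-", length(x$folds), "fold subject-wise cross-validation\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
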