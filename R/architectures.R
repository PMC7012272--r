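# Declarative model configurations, model construction on top of the CNN
# engine, and closed-form flatten-unit / parameter accounting.

MODEL_KINDS <- c("m2d", "s2d", "mv2d", "conv1d", "conv3d", "conv3d_sep")

#' Architecture configuration
#'
#' Declares one of the six network families at a given volume shape. All
#' six share the same two-stage convolutional trunk: two convolution
#' layers of 16 and 32 kernels of size 3 (valid padding, i.e. no padding),
#' each followed by leaky-ReLU, a max-pooling layer of size 2 (stride 2,
#' floor) and a normalization layer; then flatten (for `m2d`,
#' concatenation of the three branch flattens), dropout of 50% of the
#' inputs, a dense layer of 128 units with leaky-ReLU and normalization,
#' and a dense softmax output over the classes.
#'
#' Normalization placement differs by family: the 1D/2D families
#' (`m2d`, `s2d`, `mv2d`, `conv1d`) carry an extra per-feature
#' normalization after the flatten/merge vector; the 3D families do not.
#' `conv3d_sep` is identical to `conv3d` except that its second
#' convolution is factorized into a depthwise 3x3x3 stage (depth
#' multiplier 1, no bias) followed by a pointwise 1x1x1 stage (with bias).
#'
#' @param model_kind One of `"m2d"`, `"s2d"`, `"mv2d"`, `"conv1d"`,
#'   `"conv3d"`, `"conv3d_sep"`.
#' @param input_dim Volume shape `(dimX, dimY, dimZ)`; the model-specific
#'   input representation is derived from it.
#' @param n_classes Number of output classes.
#' @param conv_channels Kernel counts of the two convolution layers.
#' @param kernel_size Kernel extent per spatial dimension.
#' @param pool_size Max-pooling window (stride equals the window).
#' @param dense_units Width of the hidden fully connected layer.
#' @param dropout Fraction of dense-layer inputs dropped during training.
#' @param leaky_slope Negative-side slope of the leaky-ReLU activation.
#' @return An `arch_config` object.
#' @export
arch_config <- function(model_kind, input_dim = c(91L, 109L, 91L),
                        n_classes = 5L, conv_channels = c(16L, 32L),
                        kernel_size = 3L, pool_size = 2L,
                        dense_units = 128L, dropout = 0.5,
                        leaky_slope = 0.3) {
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  input_dim <- as.integer(input_dim)
  stopifnot(length(input_dim) == 3L, all(input_dim >= 1L))
  structure(list(model_kind = model_kind,
                 input_dim = input_dim,
                 n_classes = as.integer(n_classes),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 dropout = dropout,
                 leaky_slope = leaky_slope,
                 norm_after_pool = TRUE,
                 norm_after_merge = model_kind %in% c("m2d", "s2d", "mv2d", "conv1d"),
                 norm_after_dense = TRUE),
            class = "arch_config")
}

# Input representation of each branch: spatial extents and channel count.
branch_specs <- function(config) {
  d <- config$input_dim
  switch(config$model_kind,
    m2d = list(list(sp = d[c(2L, 3L)], C = d[1L]),
               list(sp = d[c(1L, 3L)], C = d[2L]),
               list(sp = d[c(1L, 2L)], C = d[3L])),
    s2d = list(list(sp = d[c(1L, 2L)], C = d[3L])),
    mv2d = list(list(sp = d[c(1L, 2L)], C = 1L)),
    conv1d = list(list(sp = d[2L] * d[3L], C = d[1L])),
    conv3d = ,
    conv3d_sep = list(list(sp = d, C = 1L)))
}

#' Flatten-unit count of the shared convolutional stack
#'
#' Applies the shape recurrence of the two-stage stack — each valid
#' convolution of size `kernel` shrinks every spatial extent by
#' `kernel - 1`, each pooling floor-divides it by `pool` — and multiplies
#' the surviving extents by the final channel count. With the defaults the
#' per-dimension map is `d -> floor((d - 2) / 2)` applied twice. This is
#' the number of units entering the fully connected layer.
#'
#' @param spatial_dims Integer vector of spatial extents (length 1-3).
#' @param n_convs Number of conv+pool stages.
#' @param kernel Convolution kernel extent.
#' @param pool Pooling window.
#' @param out_channels Channel count after the last stage.
#' @return Integer unit count.
#' @examples
#' conv_stack_units(c(91, 109))      # 16800
#' conv_stack_units(c(91, 109, 91))  # 352800
#' @export
conv_stack_units <- function(spatial_dims, n_convs = 2L, kernel = 3L,
                             pool = 2L, out_channels = 32L) {
  d <- as.integer(spatial_dims)
  for (i in seq_len(n_convs)) {
    d <- d - (kernel - 1L)
    if (any(d < 1L)) stop("spatial dimension collapsed below 1 at conv stage ", i)
    d <- d %/% pool
    if (any(d < 1L)) stop("spatial dimension collapsed below 1 at pool stage ", i)
  }
  prod(d) * as.integer(out_channels)
}

# Spatial dims after stage i of the conv stack.
stack_dims_after <- function(sp, stage, kernel = 3L, pool = 2L) {
  d <- as.integer(sp)
  for (i in seq_len(stage)) {
    d <- d - (kernel - 1L)
    d <- d %/% pool
  }
  d
}

#' Closed-form parameter count
#'
#' Walks the configuration's layer list and computes every layer's
#' parameter count arithmetically, without building the model:
#' convolution `prod(kernel) * C_in * C_out + C_out`; depthwise
#' convolution `prod(kernel) * C_in` (no bias); pointwise convolution
#' `C_in * C_out + C_out`; normalization 4 per normalized feature (scale,
#' shift, running mean, running variance); dense `in * out + out`. The
#' total includes the non-trainable running statistics.
#'
#' @param config An `arch_config`.
#' @return A `count_report`: list with `flatten_units` (merge length for
#'   `m2d`), `total_parameters`, and `per_layer` (data frame of layer name
#'   and count).
#' @export
count_parameters_closed_form <- function(config) {
  k <- config$kernel_size
  ch <- config$conv_channels
  specs <- branch_specs(config)
  rows <- list()
  add <- function(name, n) rows[[length(rows) + 1L]] <<- data.frame(layer = name, count = n)
  flat_total <- 0L
  for (bi in seq_along(specs)) {
    sp <- specs[[bi]]$sp
    nd <- length(sp)
    c_in <- specs[[bi]]$C
    pre <- if (length(specs) > 1L) paste0("branch", bi, "_") else ""
    add(paste0(pre, "conv1"), k^nd * c_in * ch[1L] + ch[1L])
    if (config$norm_after_pool) add(paste0(pre, "bn1"), 4L * ch[1L])
    if (config$model_kind == "conv3d_sep") {
      add(paste0(pre, "conv2_depthwise"), k^nd * ch[1L])
      add(paste0(pre, "conv2_pointwise"), ch[1L] * ch[2L] + ch[2L])
    } else {
      add(paste0(pre, "conv2"), k^nd * ch[1L] * ch[2L] + ch[2L])
    }
    if (config$norm_after_pool) add(paste0(pre, "bn2"), 4L * ch[2L])
    flat_total <- flat_total +
      conv_stack_units(sp, kernel = k, pool = config$pool_size,
                       out_channels = ch[2L])
  }
  if (config$norm_after_merge) add("bn_merge", 4L * flat_total)
  add("dense1", flat_total * config$dense_units + config$dense_units)
  if (config$norm_after_dense) add("bn_dense", 4L * config$dense_units)
  add("dense_out", config$dense_units * config$n_classes + config$n_classes)
  per_layer <- do.call(rbind, rows)
  structure(list(flatten_units = flat_total,
                 total_parameters = sum(per_layer$count),
                 per_layer = per_layer),
            class = "count_report")
}

#' Build a trainable model from a configuration
#'
#' Instantiates the network described by an [arch_config()] on the CNN
#' engine. The forward pass maps a batch of the configuration's input
#' representation to per-class probabilities (softmax output). Layer
#' order per branch: conv, leaky-ReLU, max-pool, normalization, twice;
#' then flatten (for `m2d` the three branch flattens are concatenated);
#' optional per-feature normalization of the merged vector; dropout;
#' dense with leaky-ReLU and normalization; dense softmax output.
#'
#' @param config An `arch_config`.
#' @return A `tp_model` object; see [predict_proba()],
#'   [model_count_parameters()], [train()].
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "arch_config"))
  k <- config$kernel_size
  ch <- config$conv_channels
  specs <- branch_specs(config)
  branches <- vector("list", length(specs))
  branch_units <- integer(length(specs))
  for (bi in seq_along(specs)) {
    sp <- specs[[bi]]$sp
    nd <- length(sp)
    c_in <- specs[[bi]]$C
    pre <- if (length(specs) > 1L) paste0("branch", bi, "_") else ""
    layers <- list(
      layer_conv(nd, k, c_in, ch[1L], name = paste0(pre, "conv1")),
      layer_leaky_relu(config$leaky_slope, name = paste0(pre, "act1")),
      layer_maxpool(nd, config$pool_size, name = paste0(pre, "pool1")))
    if (config$norm_after_pool) {
      layers <- c(layers, list(layer_batchnorm(ch[1L], "channel",
                                               name = paste0(pre, "bn1"))))
    }
    if (config$model_kind == "conv3d_sep") {
      layers <- c(layers, list(
        layer_depthwise_conv(nd, k, ch[1L], name = paste0(pre, "conv2_depthwise")),
        layer_conv(nd, 1L, ch[1L], ch[2L], name = paste0(pre, "conv2_pointwise"))))
    } else {
      layers <- c(layers, list(layer_conv(nd, k, ch[1L], ch[2L],
                                          name = paste0(pre, "conv2"))))
    }
    layers <- c(layers, list(
      layer_leaky_relu(config$leaky_slope, name = paste0(pre, "act2")),
      layer_maxpool(nd, config$pool_size, name = paste0(pre, "pool2"))))
    if (config$norm_after_pool) {
      layers <- c(layers, list(layer_batchnorm(ch[2L], "channel",
                                               name = paste0(pre, "bn2"))))
    }
    layers <- c(layers, list(layer_flatten(name = paste0(pre, "flatten"))))
    layers[[1L]]$is_input_layer <- TRUE
    branches[[bi]] <- layers
    branch_units[bi] <- conv_stack_units(sp, kernel = k, pool = config$pool_size,
                                         out_channels = ch[2L])
  }
  merge_units <- sum(branch_units)
  trunk <- list()
  if (config$norm_after_merge) {
    trunk <- c(trunk, list(layer_batchnorm(merge_units, "feature", name = "bn_merge")))
  }
  trunk <- c(trunk, list(
    layer_dropout(config$dropout, name = "dropout"),
    layer_dense(merge_units, config$dense_units, name = "dense1"),
    layer_leaky_relu(config$leaky_slope, name = "act_dense")))
  if (config$norm_after_dense) {
    trunk <- c(trunk, list(layer_batchnorm(config$dense_units, "feature",
                                           name = "bn_dense")))
  }
  trunk <- c(trunk, list(layer_dense(config$dense_units, config$n_classes,
                                     name = "dense_out")))
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$branches <- branches
  m$trunk <- trunk
  m$branch_units <- branch_units
  m$merge_units <- merge_units
  class(m) <- "tp_model"
  m
}

model_layers <- function(model) c(unlist(model$branches, use.names = FALSE),
                                  model$trunk)

# Forward pass to class probabilities. `inputs` is a list with one batched
# array per branch (a bare array is accepted for single-branch models).
model_forward <- function(model, inputs, training = FALSE) {
  if (!is.list(inputs)) inputs <- list(inputs)
  if (length(inputs) != length(model$branches)) {
    stop(new_error(paste0("model expects ", length(model$branches),
                          " input branch(es), got ", length(inputs)),
                   "triplanar_bad_input"))
  }
  flats <- vector("list", length(inputs))
  for (bi in seq_along(inputs)) {
    h <- inputs[[bi]]
    for (l in model$branches[[bi]]) h <- layer_forward(l, h, training)
    flats[[bi]] <- h
  }
  h <- do.call(cbind, flats)
  for (l in model$trunk) h <- layer_forward(l, h, training)
  softmax(h)
}

# Backward pass from d(loss)/d(logits); fills layer grads.
model_backward <- function(model, dlogits) {
  g <- dlogits
  for (l in rev(model$trunk)) g <- layer_backward(l, g)
  splits <- cumsum(model$branch_units)
  starts <- c(1L, head(splits, -1L) + 1L)
  for (bi in seq_along(model$branches)) {
    gb <- g[, starts[bi]:splits[bi], drop = FALSE]
    for (l in rev(model$branches[[bi]])) gb <- layer_backward(l, gb)
  }
  invisible(NULL)
}

#' Class probabilities for a batch
#'
#' Runs the model in inference mode (dropout off, normalization using
#' running statistics) and returns the per-class probability matrix.
#'
#' @param model A `tp_model`.
#' @param inputs Batched input representation as produced by
#'   [prepare_inputs()].
#' @return An `N x n_classes` matrix; rows sum to one.
#' @export
predict_proba <- function(model, inputs) {
  model_forward(model, inputs, training = FALSE)
}

#' Batch the model-specific input representation
#'
#' Applies the configuration's slicing transform to every sample in a
#' `sample_set` and stacks the results into the batched arrays the engine
#' consumes (batch index last).
#'
#' @param set A `sample_set`.
#' @param model_kind One of `MODEL_KINDS`, or an `arch_config`.
#' @return A list with one batched array per branch.
#' @export
prepare_inputs <- function(set, model_kind) {
  if (inherits(model_kind, "arch_config")) model_kind <- model_kind$model_kind
  model_kind <- match.arg(model_kind, MODEL_KINDS)
  v <- set$volumes
  d <- dim(v)
  stopifnot(length(d) == 4L)
  n <- d[4L]
  switch(model_kind,
    m2d = list(aperm(v, c(2L, 3L, 1L, 4L)),
               aperm(v, c(1L, 3L, 2L, 4L)),
               v),
    s2d = list(v),
    mv2d = list(array(rowMeans(aperm(v, c(1L, 2L, 4L, 3L)), dims = 3L),
                      c(d[1L], d[2L], 1L, n))),
    conv1d = list(aperm(array(v, c(d[1L], d[2L] * d[3L], n)), c(2L, 1L, 3L))),
    conv3d = ,
    conv3d_sep = list(array(v, c(d[1L], d[2L], d[3L], 1L, n))))
}

#' Count the parameters of a built model
#'
#' Enumerates every layer of a built model and sums the lengths of its
#' parameter arrays, including the running mean and variance buffers of
#' the normalization layers. This count is obtained from the model object
#' itself, independently of the closed-form arithmetic in
#' [count_parameters_closed_form()].
#'
#' @param model A `tp_model`.
#' @return A `count_report` (with `flatten_units` taken from the model's
#'   merge width).
#' @export
model_count_parameters <- function(model) {
  layers <- model_layers(model)
  per_layer <- do.call(rbind, lapply(layers, function(l) {
    data.frame(layer = l$name, count = layer_param_count(l))
  }))
  per_layer <- per_layer[per_layer$count > 0L, , drop = FALSE]
  rownames(per_layer) <- NULL
  structure(list(flatten_units = model$merge_units,
                 total_parameters = sum(per_layer$count),
                 per_layer = per_layer),
            class = "count_report")
}

#' Verify closed-form counts against a built model
#'
#' Builds the model for a configuration, counts its parameters by
#' enumeration, and compares with the closed-form arithmetic. The two
#' code paths are independent, so agreement validates both.
#'
#' @param config An `arch_config`.
#' @return A list: `ok` (logical), `closed_form` and `built`
#'   (`count_report`s), and `diff` (per-layer rows where the counts
#'   disagree, `NULL` when `ok`).
#' @export
verify_counts <- function(config) {
  cf <- count_parameters_closed_form(config)
  model <- build_model(config)
  bc <- model_count_parameters(model)
  merged <- merge(cf$per_layer, bc$per_layer, by = "layer",
                  all = TRUE, suffixes = c("_closed", "_built"))
  bad <- merged[is.na(merged$count_closed) | is.na(merged$count_built) |
                  merged$count_closed != merged$count_built, , drop = FALSE]
  ok <- nrow(bad) == 0L && cf$total_parameters == bc$total_parameters
  list(ok = ok, closed_form = cf, built = bc,
       diff = if (ok) NULL else bad)
}

#' @export
print.count_report <- function(x, ...) {
  cat("units entering the fully connected layer:",
      format(x$flatten_units, big.mark = ","), "\n")
  cat("total parameters:", format(x$total_parameters, big.mark = ","), "\n")
  print(x$per_layer, row.names = FALSE)
  invisible(x)
}
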