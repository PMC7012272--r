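# Minimal CNN engine: n-dimensional valid convolution via im2col + GEMM,
# max pooling, batch normalization with running statistics, dropout, dense
# layers, and an Adam optimizer. Batches are stored channels-last with the
# batch index as the final array dimension: (spatial..., C, N) for
# convolutional tensors and (N, F) matrices for flat features.

# ---- im2col / col2im --------------------------------------------------------

# Patch matrix for a valid convolution. X: array (spatial..., C, N), k: kernel
# extent per spatial dim. Rows are ordered position-fastest then sample;
# columns are ordered kernel-offset-fastest then input channel, matching the
# vec order of a weight array with dim c(k, C_in, C_out).
im2col <- function(X, k) {
  d <- dim(X)
  nd <- length(k)
  sp <- d[seq_len(nd)]
  C <- d[nd + 1L]
  N <- d[nd + 2L]
  o <- sp - k + 1L
  if (any(o < 1L)) stop("spatial dimension collapses below 1 under valid convolution")
  offs <- as.matrix(expand.grid(lapply(k, seq_len)))
  cols <- matrix(0, prod(o) * N, prod(k) * C)
  col <- 0L
  for (c in seq_len(C)) {
    for (j in seq_len(nrow(offs))) {
      t <- offs[j, ]
      col <- col + 1L
      cols[, col] <- switch(nd,
        X[t[1L]:(t[1L] + o[1L] - 1L), c, , drop = FALSE],
        X[t[1L]:(t[1L] + o[1L] - 1L), t[2L]:(t[2L] + o[2L] - 1L), c, , drop = FALSE],
        X[t[1L]:(t[1L] + o[1L] - 1L), t[2L]:(t[2L] + o[2L] - 1L),
          t[3L]:(t[3L] + o[3L] - 1L), c, , drop = FALSE])
    }
  }
  cols
}

# Scatter-add inverse of im2col: accumulate column gradients back onto the
# input array positions.
col2im <- function(dcols, dims, k) {
  nd <- length(k)
  sp <- dims[seq_len(nd)]
  C <- dims[nd + 1L]
  N <- dims[nd + 2L]
  o <- sp - k + 1L
  offs <- as.matrix(expand.grid(lapply(k, seq_len)))
  dX <- array(0, dims)
  col <- 0L
  for (c in seq_len(C)) {
    for (j in seq_len(nrow(offs))) {
      t <- offs[j, ]
      col <- col + 1L
      g <- array(dcols[, col], c(o, N))
      if (nd == 1L) {
        i1 <- t[1L]:(t[1L] + o[1L] - 1L)
        dX[i1, c, ] <- dX[i1, c, ] + g
      } else if (nd == 2L) {
        i1 <- t[1L]:(t[1L] + o[1L] - 1L)
        i2 <- t[2L]:(t[2L] + o[2L] - 1L)
        dX[i1, i2, c, ] <- dX[i1, i2, c, ] + g
      } else {
        i1 <- t[1L]:(t[1L] + o[1L] - 1L)
        i2 <- t[2L]:(t[2L] + o[2L] - 1L)
        i3 <- t[3L]:(t[3L] + o[3L] - 1L)
        dX[i1, i2, i3, c, ] <- dX[i1, i2, i3, c, ] + g
      }
    }
  }
  dX
}

# ---- layer objects ----------------------------------------------------------

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$name <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  if (is.null(e$buffers)) e$buffers <- list()
  e$grads <- list()
  e$cache <- NULL
  class(e) <- c(paste0("tp_", type), "tp_layer")
  e
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' @keywords internal
layer_conv <- function(nd, k, c_in, c_out, bias = TRUE, name = "conv") {
  k <- rep_len(as.integer(k), nd)
  K <- prod(k) * c_in
  l <- new_layer("conv", nd = nd, k = k, c_in = c_in, c_out = c_out,
                 use_bias = bias, name = name)
  l$params$W <- glorot_uniform(c(K, c_out), K, prod(k) * c_out)
  if (bias) l$params$b <- numeric(c_out)
  l
}

#' @keywords internal
layer_depthwise_conv <- function(nd, k, c_in, name = "depthwise_conv") {
  k <- rep_len(as.integer(k), nd)
  l <- new_layer("depthwise", nd = nd, k = k, c_in = c_in, c_out = c_in,
                 name = name)
  # depth multiplier 1, no bias
  l$params$W <- glorot_uniform(c(prod(k), c_in), prod(k), prod(k))
  l
}

#' @keywords internal
layer_leaky_relu <- function(slope = 0.3, name = "leaky_relu") {
  new_layer("leaky", slope = slope, name = name)
}

#' @keywords internal
layer_maxpool <- function(nd, size = 2L, name = "maxpool") {
  new_layer("maxpool", nd = nd, size = as.integer(size), name = name)
}

#' @keywords internal
layer_batchnorm <- function(n_features, mode = c("channel", "feature"),
                            momentum = 0.9, eps = 1e-3, name = "batchnorm") {
  mode <- match.arg(mode)
  l <- new_layer("batchnorm", mode = mode, momentum = momentum, eps = eps,
                 n_features = n_features, name = name)
  l$params$gamma <- rep(1, n_features)
  l$params$beta <- rep(0, n_features)
  l$buffers$running_mean <- rep(0, n_features)
  l$buffers$running_var <- rep(1, n_features)
  l
}

#' @keywords internal
layer_flatten <- function(name = "flatten") new_layer("flatten", name = name)

#' @keywords internal
layer_dropout <- function(p = 0.5, name = "dropout") {
  new_layer("dropout", p = p, name = name)
}

#' @keywords internal
layer_dense <- function(n_in, n_out, name = "dense") {
  l <- new_layer("dense", n_in = n_in, n_out = n_out, name = name)
  l$params$W <- glorot_uniform(c(n_in, n_out), n_in, n_out)
  l$params$b <- numeric(n_out)
  l
}

# ---- forward ----------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  UseMethod("layer_forward")
}

#' @export
layer_forward.tp_conv <- function(layer, x, training = FALSE) {
  nd <- layer$nd
  d <- dim(x)
  stopifnot(length(d) == nd + 2L, d[nd + 1L] == layer$c_in)
  o <- d[seq_len(nd)] - layer$k + 1L
  N <- d[nd + 2L]
  cols <- im2col(x, layer$k)
  y <- cols %*% layer$params$W
  if (layer$use_bias) y <- sweep(y, 2L, layer$params$b, "+")
  y <- aperm(array(y, c(o, N, layer$c_out)), c(seq_len(nd), nd + 2L, nd + 1L))
  if (training) layer$cache <- list(cols = cols, dims = d)
  y
}

#' @export
layer_forward.tp_depthwise <- function(layer, x, training = FALSE) {
  nd <- layer$nd
  d <- dim(x)
  C <- d[nd + 1L]
  N <- d[nd + 2L]
  o <- d[seq_len(nd)] - layer$k + 1L
  y <- array(0, c(o, C, N))
  cols_list <- if (training) vector("list", C) else NULL
  for (c in seq_len(C)) {
    xc <- switch(nd,
      x[, c, , drop = FALSE],
      x[, , c, , drop = FALSE],
      x[, , , c, , drop = FALSE])
    cols <- im2col(array(xc, c(d[seq_len(nd)], 1L, N)), layer$k)
    yc <- array(cols %*% layer$params$W[, c, drop = FALSE], c(o, N))
    if (nd == 1L) y[, c, ] <- yc
    else if (nd == 2L) y[, , c, ] <- yc
    else y[, , , c, ] <- yc
    if (training) cols_list[[c]] <- cols
  }
  if (training) layer$cache <- list(cols = cols_list, dims = d)
  y
}

#' @export
layer_forward.tp_leaky <- function(layer, x, training = FALSE) {
  neg <- x < 0
  y <- x
  y[neg] <- layer$slope * x[neg]
  if (training) layer$cache <- list(neg = neg)
  y
}

#' @export
layer_forward.tp_maxpool <- function(layer, x, training = FALSE) {
  nd <- layer$nd
  s <- layer$size
  d <- dim(x)
  sp <- d[seq_len(nd)]
  o <- sp %/% s
  rest <- d[(nd + 1L):length(d)]
  offs <- as.matrix(expand.grid(rep(list(seq_len(s) - 1L), nd)))
  ncand <- nrow(offs)
  ncells <- prod(o) * prod(rest)
  cand <- matrix(0, ncells, ncand)
  cidx <- if (training) matrix(0L, ncells, ncand) else NULL
  lin <- if (training) array(seq_along(x), d) else NULL
  for (j in seq_len(ncand)) {
    ix <- lapply(seq_len(nd), function(i) seq(offs[j, i] + 1L, by = s, length.out = o[i]))
    sl <- switch(nd,
      x[ix[[1L]], , , drop = FALSE],
      x[ix[[1L]], ix[[2L]], , , drop = FALSE],
      x[ix[[1L]], ix[[2L]], ix[[3L]], , , drop = FALSE])
    cand[, j] <- sl
    if (training) {
      li <- switch(nd,
        lin[ix[[1L]], , , drop = FALSE],
        lin[ix[[1L]], ix[[2L]], , , drop = FALSE],
        lin[ix[[1L]], ix[[2L]], ix[[3L]], , , drop = FALSE])
      cidx[, j] <- li
    }
  }
  amax <- max.col(cand, ties.method = "first")
  y <- array(cand[cbind(seq_len(ncells), amax)], c(o, rest))
  if (training) layer$cache <- list(cidx = cidx, amax = amax, dims = d)
  y
}

#' @export
layer_forward.tp_batchnorm <- function(layer, x, training = FALSE) {
  eps <- layer$eps
  if (layer$mode == "channel") {
    d <- dim(x)
    nd <- length(d) - 2L
    C <- d[nd + 1L]
    stopifnot(C == layer$n_features)
    P <- prod(d[seq_len(nd)])
    N <- d[nd + 2L]
    xr <- array(x, c(P, C, N))
    if (training) {
      mu <- rowMeans(colMeans(xr))
      v <- rowMeans(colMeans(xr^2)) - mu^2
      v <- pmax(v, 0)
      layer$buffers$running_mean <- layer$momentum * layer$buffers$running_mean +
        (1 - layer$momentum) * mu
      layer$buffers$running_var <- layer$momentum * layer$buffers$running_var +
        (1 - layer$momentum) * v
    } else {
      mu <- layer$buffers$running_mean
      v <- layer$buffers$running_var
    }
    sd_ <- sqrt(v + eps)
    xhat <- sweep(sweep(xr, 2L, mu, "-"), 2L, sd_, "/")
    y <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
    if (training) layer$cache <- list(xhat = xhat, sd_ = sd_, dims = d, B = P * N)
    array(y, d)
  } else {
    stopifnot(ncol(x) == layer$n_features)
    if (training) {
      mu <- colMeans(x)
      v <- colMeans(x^2) - mu^2
      v <- pmax(v, 0)
      layer$buffers$running_mean <- layer$momentum * layer$buffers$running_mean +
        (1 - layer$momentum) * mu
      layer$buffers$running_var <- layer$momentum * layer$buffers$running_var +
        (1 - layer$momentum) * v
    } else {
      mu <- layer$buffers$running_mean
      v <- layer$buffers$running_var
    }
    sd_ <- sqrt(v + eps)
    xhat <- sweep(sweep(x, 2L, mu, "-"), 2L, sd_, "/")
    y <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
    if (training) layer$cache <- list(xhat = xhat, sd_ = sd_, B = nrow(x))
    y
  }
}

#' @export
layer_forward.tp_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  N <- d[length(d)]
  if (training) layer$cache <- list(dims = d)
  t(matrix(x, prod(d[-length(d)]), N))
}

#' @export
layer_forward.tp_dropout <- function(layer, x, training = FALSE) {
  if (!training) return(x)
  keep <- stats::runif(length(x)) >= layer$p
  layer$cache <- list(keep = keep)
  x * keep / (1 - layer$p)
}

#' @export
layer_forward.tp_dense <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- list(x = x)
  sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
}

# ---- backward ---------------------------------------------------------------

layer_backward <- function(layer, dy) UseMethod("layer_backward")

#' @export
layer_backward.tp_conv <- function(layer, dy) {
  nd <- layer$nd
  cache <- layer$cache
  d <- cache$dims
  o <- d[seq_len(nd)] - layer$k + 1L
  N <- d[nd + 2L]
  dym <- matrix(aperm(dy, c(seq_len(nd), nd + 2L, nd + 1L)), prod(o) * N, layer$c_out)
  layer$grads$W <- crossprod(cache$cols, dym)
  if (layer$use_bias) layer$grads$b <- colSums(dym)
  if (isTRUE(layer$is_input_layer)) return(NULL)  # input gradient never consumed
  dcols <- tcrossprod(dym, layer$params$W)
  col2im(dcols, d, layer$k)
}

#' @export
layer_backward.tp_depthwise <- function(layer, dy) {
  nd <- layer$nd
  cache <- layer$cache
  d <- cache$dims
  C <- d[nd + 1L]
  N <- d[nd + 2L]
  o <- d[seq_len(nd)] - layer$k + 1L
  dX <- array(0, d)
  dW <- matrix(0, prod(layer$k), C)
  for (c in seq_len(C)) {
    dyc <- switch(nd,
      dy[, c, , drop = FALSE],
      dy[, , c, , drop = FALSE],
      dy[, , , c, , drop = FALSE])
    dycv <- matrix(as.vector(dyc), prod(o) * N, 1L)
    cols <- cache$cols[[c]]
    dW[, c] <- crossprod(cols, dycv)
    dcols <- tcrossprod(dycv, layer$params$W[, c, drop = FALSE])
    dxc <- col2im(dcols, c(d[seq_len(nd)], 1L, N), layer$k)
    if (nd == 1L) dX[, c, ] <- dxc
    else if (nd == 2L) dX[, , c, ] <- dxc
    else dX[, , , c, ] <- dxc
  }
  layer$grads$W <- dW
  dX
}

#' @export
layer_backward.tp_leaky <- function(layer, dy) {
  dx <- dy
  dx[layer$cache$neg] <- layer$slope * dy[layer$cache$neg]
  dx
}

#' @export
layer_backward.tp_maxpool <- function(layer, dy) {
  cache <- layer$cache
  dxv <- numeric(prod(cache$dims))
  dyv <- as.vector(dy)
  for (j in seq_len(ncol(cache$cidx))) {
    rows <- which(cache$amax == j)
    if (length(rows)) dxv[cache$cidx[rows, j]] <- dyv[rows]
  }
  array(dxv, cache$dims)
}

#' @export
layer_backward.tp_batchnorm <- function(layer, dy) {
  cache <- layer$cache
  g <- layer$params$gamma
  if (layer$mode == "channel") {
    d <- cache$dims
    nd <- length(d) - 2L
    C <- d[nd + 1L]
    P <- prod(d[seq_len(nd)])
    N <- d[nd + 2L]
    dyr <- array(dy, c(P, C, N))
    xhat <- cache$xhat
    layer$grads$gamma <- rowSums(colSums(dyr * xhat))
    layer$grads$beta <- rowSums(colSums(dyr))
    dxhat <- sweep(dyr, 2L, g, "*")
    B <- cache$B
    mdx <- rowSums(colSums(dxhat)) / B
    mdxx <- rowSums(colSums(dxhat * xhat)) / B
    dx <- sweep(dxhat, 2L, mdx, "-") - sweep(xhat, 2L, mdxx, "*")
    dx <- sweep(dx, 2L, cache$sd_, "/")
    array(dx, d)
  } else {
    xhat <- cache$xhat
    layer$grads$gamma <- colSums(dy * xhat)
    layer$grads$beta <- colSums(dy)
    dxhat <- sweep(dy, 2L, g, "*")
    B <- cache$B
    mdx <- colMeans(dxhat)
    mdxx <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2L, mdx, "-") - sweep(xhat, 2L, mdxx, "*")
    sweep(dx, 2L, cache$sd_, "/")
  }
}

#' @export
layer_backward.tp_flatten <- function(layer, dy) {
  array(t(dy), layer$cache$dims)
}

#' @export
layer_backward.tp_dropout <- function(layer, dy) {
  if (is.null(layer$cache)) return(dy)
  dy * layer$cache$keep / (1 - layer$p)
}

#' @export
layer_backward.tp_dense <- function(layer, dy) {
  layer$grads$W <- crossprod(layer$cache$x, dy)
  layer$grads$b <- colSums(dy)
  tcrossprod(dy, layer$params$W)
}

# ---- optimizer --------------------------------------------------------------

adam_init <- function(layers) {
  for (l in layers) {
    l$opt <- lapply(l$params, function(p) list(m = array(0, dim(p) %||% length(p)),
                                               v = array(0, dim(p) %||% length(p))))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[nm]] <- st
      l$params[[nm]] <- l$params[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(NULL)
}

clear_caches <- function(layers) {
  for (l in layers) {
    l$cache <- NULL
    l$grads <- list()
  }
  invisible(NULL)
}

# ---- parameter accounting ---------------------------------------------------

layer_param_count <- function(layer) {
  sum(vapply(layer$params, length, integer(1)),
      vapply(layer$buffers, length, integer(1)))
}

#' Numerically stable softmax
#'
#' Maps a vector of real-valued scores (logits) to a probability vector:
#' `exp(z_j) / sum_k exp(z_k)`, computed after subtracting the maximum so
#' that large scores do not overflow. For a matrix, rows are treated as
#' independent score vectors.
#'
#' @param z A numeric vector of logits, or a matrix with one score vector
#'   per row.
#' @return A vector (or matrix) of the same shape whose (row) entries are
#'   positive and sum to one.
#' @examples
#' softmax(c(0, log(2)))  # 1/3, 2/3
#' @export
softmax <- function(z) {
  if (is.matrix(z)) {
    zs <- z - apply(z, 1L, max)
    e <- exp(zs)
    e / rowSums(e)
  } else {
    zs <- z - max(z)
    e <- exp(zs)
    e / sum(e)
  }
}
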