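# Compact neural-network engine for patch classifiers.
#
# Activations flow as 4-D arrays (n, h, w, c) until `flatten`, then as
# (n, features) matrices. Each layer has a forward pass returning the output
# plus a cache, and a backward pass returning the input gradient plus
# parameter gradients; training is plain minibatch Adam on softmax
# cross-entropy. Everything is vectorized base R: the patch geometries this
# package targets (3x3xD windows, a few thousand samples) never justify
# heavier machinery.

# ---- batched im2col / col2im ------------------------------------------------

pad4 <- function(x, ph0, ph1, pw0, pw1) {
  if (ph0 + ph1 + pw0 + pw1 == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + ph0 + ph1, d[3L] + pw0 + pw1, d[4L]))
  out[, ph0 + seq_len(d[2L]), pw0 + seq_len(d[3L]), ] <- x
  out
}

same_pad <- function(h, k, stride) {
  out <- ceiling(h / stride)
  tot <- max(0L, (out - 1L) * stride + k - h)
  c(tot %/% 2L, tot - tot %/% 2L)
}

# x: (n, h, w, c) -> list(mat = (n*ho*wo, k*k*c), ho, wo, padded dims)
# column order matches as.vector of a (k, k, c) kernel window.
batch_im2col <- function(x, k, stride, padding = "valid") {
  d <- dim(x)
  if (padding == "same") {
    ph <- same_pad(d[2L], k, stride); pw <- same_pad(d[3L], k, stride)
  } else ph <- pw <- c(0L, 0L)
  xp <- pad4(x, ph[1L], ph[2L], pw[1L], pw[2L])
  dp <- dim(xp)
  ho <- (dp[2L] - k) %/% stride + 1L
  wo <- (dp[3L] - k) %/% stride + 1L
  if (ho < 1L || wo < 1L)
    stop(sprintf("window %d too large for input %d x %d", k, d[2L], d[3L]),
         call. = FALSE)
  n <- d[1L]; ch <- d[4L]
  col <- array(0, c(n, ho, wo, k * k * ch))
  for (dr in seq_len(k)) for (dc in seq_len(k)) {
    rs <- seq.int(dr, by = stride, length.out = ho)
    cs <- seq.int(dc, by = stride, length.out = wo)
    cols <- dr + (dc - 1L) * k + (seq_len(ch) - 1L) * k * k
    col[, , , cols] <- xp[, rs, cs, , drop = FALSE]
  }
  list(mat = matrix(col, n * ho * wo, k * k * ch),
       ho = ho, wo = wo, pdim = dp, ph = ph, pw = pw, k = k,
       stride = stride, n = n, ch = ch)
}

# scatter-add the column gradient back to the (padded, then cropped) input
batch_col2im <- function(dmat, info) {
  k <- info$k; stride <- info$stride; ch <- info$ch
  n <- info$n; ho <- info$ho; wo <- info$wo
  dcol <- array(dmat, c(n, ho, wo, k * k * ch))
  dxp <- array(0, info$pdim)
  for (dr in seq_len(k)) for (dc in seq_len(k)) {
    rs <- seq.int(dr, by = stride, length.out = ho)
    cs <- seq.int(dc, by = stride, length.out = wo)
    cols <- dr + (dc - 1L) * k + (seq_len(ch) - 1L) * k * k
    dxp[, rs, cs, ] <- dxp[, rs, cs, , drop = FALSE] +
      dcol[, , , cols, drop = FALSE]
  }
  d <- info$pdim
  dxp[, info$ph[1L] + seq_len(d[2L] - sum(info$ph)),
      info$pw[1L] + seq_len(d[3L] - sum(info$pw)), , drop = FALSE]
}

# ---- layer forward/backward -------------------------------------------------

layer_forward <- function(layer, params, x, training) {
  switch(layer$type,
    scs = {
      info <- batch_im2col(x, layer$kernel_size, layer$stride, "valid")
      Xcol <- info$mat
      W <- params$W; q <- params$q; p <- params$p
      xn <- sqrt(rowSums(Xcol^2))
      wn <- sqrt(colSums(W^2))
      dot <- Xcol %*% W
      den <- outer(xn + 0, wn) + outer(xn, q) +
        matrix(wn * q + q * q, nrow(dot), ncol(W), byrow = TRUE)
      cc <- dot / den
      pm <- matrix(p, nrow(cc), ncol(cc), byrow = TRUE)
      s <- sign(cc) * abs(cc)^pm
      out <- array(s, c(info$n, info$ho, info$wo, ncol(W)))
      list(out = out,
           cache = list(info = info, Xcol = Xcol, xn = xn, wn = wn,
                        cc = cc, den = den, s = s))
    },
    conv = {
      info <- batch_im2col(x, layer$kernel_size, layer$stride, layer$padding)
      out_mat <- info$mat %*% params$W +
        matrix(params$b, nrow(info$mat), length(params$b), byrow = TRUE)
      list(out = array(out_mat, c(info$n, info$ho, info$wo, ncol(params$W))),
           cache = list(info = info))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    flatten = {
      d <- dim(x)
      list(out = matrix(x, d[1L], prod(d[-1L])), cache = list(dims = d))
    },
    dense = {
      out <- x %*% params$W +
        matrix(params$b, nrow(x), length(params$b), byrow = TRUE)
      list(out = out, cache = list(x = x))
    },
    batchnorm = {
      eps <- 1e-5
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(sweep(x, 2L, mu)^2)
      } else {
        mu <- params$run_mean
        v <- params$run_var
      }
      xhat <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + eps), "/")
      out <- sweep(sweep(xhat, 2L, params$gamma, "*"), 2L, params$beta, "+")
      list(out = out,
           cache = list(xhat = xhat, var = v, mu = mu, x = x,
                        training = training))
    },
    pool = {
      pool_forward(x, layer$window, layer$stride, layer$kind)
    },
    identity = list(out = x, cache = list())
  )
}

pool_forward <- function(x, window, stride, kind) {
  d <- dim(x)
  ho <- (d[2L] - window) %/% stride + 1L
  wo <- (d[3L] - window) %/% stride + 1L
  out <- array(0, c(d[1L], ho, wo, d[4L]))
  sel <- NULL
  if (kind != "avg") sel <- array(0L, c(d[1L], ho, wo, d[4L], 2L))
  for (r in seq_len(ho)) for (c in seq_len(wo)) {
    rs <- (r - 1L) * stride + seq_len(window)
    cs <- (c - 1L) * stride + seq_len(window)
    win <- x[, rs, cs, , drop = FALSE]           # (n, window, window, ch)
    if (kind == "avg") {
      out[, r, c, ] <- apply(win, c(1L, 4L), mean)
    } else {
      n <- d[1L]; ch <- d[4L]
      wm <- matrix(aperm(win, c(1L, 4L, 3L, 2L)), n * ch, window * window)
      # columns now scan the window row-major (row fastest last) so
      # which.max honors the first-in-row-major tie rule
      key <- if (kind == "absmax") abs(wm) else wm
      pick <- max.col(key, ties.method = "first")
      val <- wm[cbind(seq_len(n * ch), pick)]
      out[, r, c, ] <- matrix(val, n, ch)
      dr <- (pick - 1L) %/% window + 1L          # row offset within window
      dc <- (pick - 1L) %% window + 1L           # col offset within window
      sel[, r, c, , 1L] <- matrix(rs[dr], n, ch)
      sel[, r, c, , 2L] <- matrix(cs[dc], n, ch)
    }
  }
  list(out = out, cache = list(kind = kind, window = window, stride = stride,
                               in_dim = d, sel = sel))
}

pool_backward <- function(cache, dout) {
  d <- cache$in_dim
  dx <- array(0, d)
  od <- dim(dout)
  if (cache$kind == "avg") {
    w2 <- cache$window^2
    for (r in seq_len(od[2L])) for (c in seq_len(od[3L])) {
      rs <- (r - 1L) * cache$stride + seq_len(cache$window)
      cs <- (c - 1L) * cache$stride + seq_len(cache$window)
      g <- dout[, r, c, , drop = FALSE] / w2
      for (dr in seq_along(rs)) for (dc in seq_along(cs))
        dx[, rs[dr], cs[dc], ] <- dx[, rs[dr], cs[dc], , drop = FALSE] + g
    }
  } else {
    n <- d[1L]; ch <- d[4L]
    for (r in seq_len(od[2L])) for (c in seq_len(od[3L])) {
      ridx <- cache$sel[, r, c, , 1L]
      cidx <- cache$sel[, r, c, , 2L]
      g <- matrix(dout[, r, c, ], n, ch)
      idx <- cbind(rep(seq_len(n), ch),
                   as.vector(ridx), as.vector(cidx),
                   rep(seq_len(ch), each = n))
      # accumulate (overlapping windows may select the same cell)
      for (i in seq_len(nrow(idx)))
        dx[idx[i, 1L], idx[i, 2L], idx[i, 3L], idx[i, 4L]] <-
          dx[idx[i, 1L], idx[i, 2L], idx[i, 3L], idx[i, 4L]] +
          as.vector(g)[i]
    }
  }
  dx
}

layer_backward <- function(layer, params, cache, dout) {
  switch(layer$type,
    scs = {
      info <- cache$info
      U <- ncol(params$W)
      G <- matrix(dout, info$n * info$ho * info$wo, U)
      pm <- matrix(params$p, nrow(G), U, byrow = TRUE)
      gc <- G * pm * abs(cache$cc)^(pm - 1)       # dL/dc
      Gdot <- gc / cache$den                       # dL/d(dot)
      negc <- -cache$cc
      wq <- cache$wn + params$q                    # length U
      xq <- outer(cache$xn, params$q, "+")         # N x U
      dW <- crossprod(cache$Xcol, Gdot)
      wn_safe <- ifelse(cache$wn > 0, cache$wn, 1)
      dwn <- colSums(gc * negc) / wq               # dL/d||w||
      dW <- dW + sweep(params$W, 2L, dwn / wn_safe, "*")
      dq <- colSums(gc * negc * (1 / xq)) + colSums(gc * negc) / wq
      logc <- ifelse(cache$cc == 0, 0, log(abs(cache$cc)))
      dp <- colSums(G * cache$s * logc)
      dxn <- rowSums(gc * negc / xq)               # dL/d||x||
      xn_safe <- ifelse(cache$xn > 0, cache$xn, 1)
      dXcol <- Gdot %*% t(params$W) + (dxn / xn_safe) * cache$Xcol
      dx <- batch_col2im(dXcol, info)
      grads <- list(W = dW)
      grads$q <- if (layer$q_trainable) dq else numeric(U)
      grads$p <- if (layer$p_trainable) dp else numeric(U)
      list(dx = dx, grads = grads)
    },
    conv = {
      info <- cache$info
      F_ <- ncol(params$W)
      G <- matrix(dout, info$n * info$ho * info$wo, F_)
      dW <- crossprod(info$mat, G)
      db <- colSums(G)
      dx <- batch_col2im(G %*% t(params$W), info)
      list(dx = dx, grads = list(W = dW, b = db))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    flatten = list(dx = array(dout, cache$dims), grads = NULL),
    dense = list(dx = dout %*% t(params$W),
                 grads = list(W = crossprod(cache$x, dout),
                              b = colSums(dout))),
    batchnorm = {
      eps <- 1e-5
      n <- nrow(dout)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2L, params$gamma, "*")
      iv <- 1 / sqrt(cache$var + eps)
      if (cache$training) {
        dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout),
                                   byrow = TRUE) -
                    cache$xhat * matrix(colMeans(dxhat * cache$xhat), n,
                                        ncol(dout), byrow = TRUE),
                    2L, iv, "*")
      } else {
        dx <- sweep(dxhat, 2L, iv, "*")
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    pool = list(dx = pool_backward(cache, dout), grads = NULL),
    identity = list(dx = dout, grads = NULL)
  )
}

# ---- model specs ------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the training regime used throughout this package:
#' 50 epochs, minibatches of 256, learning rate 0.001, Adam, softmax
#' cross-entropy loss.
#'
#' @param epochs number of passes over the training split.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is supported.
#' @param loss only `"softmax_cross_entropy"` is supported.
#' @param seed integer seed controlling initialization and shuffling.
#' @return An object of class `training_config`.
#' @export
training_config <- function(epochs = 50L, batch_size = 256L,
                            learning_rate = 0.001, optimizer = "adam",
                            loss = "softmax_cross_entropy", seed = 1L) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0)
  optimizer <- match.arg(optimizer, "adam")
  loss <- match.arg(loss, "softmax_cross_entropy")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, seed = as.integer(seed)),
            class = "training_config")
}

model_spec <- function(layers, input_shape, n_classes, name) {
  structure(list(layers = layers, input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), name = name),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s'> input (%s) -> %d classes\n", x$name,
              paste(x$input_shape, collapse = ", "), x$n_classes))
  for (ly in x$layers) cat("  -", ly$type,
    if (!is.null(ly$n_units)) sprintf("[%d units]", ly$n_units) else
    if (!is.null(ly$filters)) sprintf("[%d filters]", ly$filters) else
    if (!is.null(ly$units)) sprintf("[%d]", ly$units) else "", "\n")
  invisible(x)
}

# spatial output side of a valid k/stride window op
out_side <- function(h, k, stride) (h - k) %/% stride + 1L

#' Build the SCS classifier
#'
#' Composition: one SCS layer (default 32 units, kernel `min(3, s)`, stride
#' 1), absolute max-pooling (window 2 where the SCS output is spatially at
#' least 2 x 2, otherwise the pooling stage is an identity), flatten, and a
#' softmax head of width `n_classes`. There are no activations or
#' normalization layers between the SCS stage and the head.
#'
#' @param input_shape integer triple (s, s, D).
#' @param n_classes number of classes C (>= 2).
#' @param layer_cfg an [scs_layer_config()]; its `kernel_size` is clamped to
#'   the patch side.
#' @return A `model_spec`.
#' @export
build_scs_classifier <- function(input_shape, n_classes,
                                 layer_cfg = scs_layer_config()) {
  input_shape <- as.integer(input_shape)
  s <- input_shape[1L]
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L)
    stop("classification needs at least 2 classes", call. = FALSE)
  k <- min(layer_cfg$kernel_size, s)
  if (k > s) stop("kernel larger than patch", call. = FALSE)
  layers <- list(list(type = "scs", n_units = layer_cfg$n_units,
                      kernel_size = k, stride = layer_cfg$stride,
                      q_init = layer_cfg$q_init, p_init = layer_cfg$p_init,
                      q_trainable = layer_cfg$q_trainable,
                      p_trainable = layer_cfg$p_trainable,
                      q_floor = layer_cfg$q_floor,
                      init = layer_cfg$init %||% "prototype"))
  side <- out_side(s, k, layer_cfg$stride)
  if (side >= 2L) {
    layers <- c(layers, list(list(type = "pool", kind = "absmax",
                                  window = 2L, stride = 2L)))
  } else {
    layers <- c(layers, list(list(type = "identity",
                                  note = "abs-max-pool degenerates to identity at 1x1")))
  }
  layers <- c(layers, list(list(type = "flatten"),
                           list(type = "dense", units = n_classes)))
  model_spec(layers, input_shape, n_classes, "scs")
}

#' Build a convolutional baseline
#'
#' `"cnn2d"`: a 3 x 3 convolution with ReLU, max-pooling (identity when the
#' feature map is already 1 x 1, with a note), flatten, a 100-neuron dense
#' layer with batch normalization and ReLU, and a softmax head. `"lenet"`:
#' two 5 x 5 convolution + ReLU + average-pooling stages followed by dense
#' layers of 120 and 84 neurons and a softmax head. Inputs smaller than a
#' kernel are handled with same-padding (noted via `message()`).
#'
#' @param name `"cnn2d"` or `"lenet"`.
#' @param input_shape integer triple (s, s, D).
#' @param n_classes number of classes (>= 2).
#' @param filters convolution width for `cnn2d` (default 32).
#' @return A `model_spec`.
#' @export
build_baseline <- function(name, input_shape, n_classes, filters = 32L) {
  input_shape <- as.integer(input_shape)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L)
    stop("classification needs at least 2 classes", call. = FALSE)
  s <- input_shape[1L]
  add_pool <- function(layers, side, kind) {
    if (side >= 2L) {
      c(layers, list(list(type = "pool", kind = kind, window = 2L,
                          stride = 2L)))
    } else {
      message(sprintf("%s pooling degenerates to identity at %d x %d",
                      kind, side, side))
      c(layers, list(list(type = "identity")))
    }
  }
  if (identical(name, "cnn2d")) {
    pad <- if (s >= 3L) "valid" else "same"
    if (pad == "same") message("input smaller than 3 x 3 kernel; same-padding")
    layers <- list(list(type = "conv", filters = as.integer(filters),
                        kernel_size = 3L, stride = 1L, padding = pad),
                   list(type = "relu"))
    side <- if (pad == "same") s else out_side(s, 3L, 1L)
    layers <- add_pool(layers, side, "max")
    layers <- c(layers, list(list(type = "flatten"),
                             list(type = "dense", units = 100L),
                             list(type = "batchnorm"),
                             list(type = "relu"),
                             list(type = "dense", units = n_classes)))
    return(model_spec(layers, input_shape, n_classes, "cnn2d"))
  }
  if (identical(name, "lenet")) {
    pad <- if (s >= 5L) "valid" else "same"
    if (pad == "same")
      message("input smaller than 5 x 5 kernels; same-padding adaptation")
    layers <- list(list(type = "conv", filters = 6L, kernel_size = 5L,
                        stride = 1L, padding = pad),
                   list(type = "relu"))
    side <- if (pad == "same") s else out_side(s, 5L, 1L)
    layers <- add_pool(layers, side, "avg")
    side <- if (side >= 2L) out_side(side, 2L, 2L) else side
    layers <- c(layers, list(list(type = "conv", filters = 16L,
                                  kernel_size = 5L, stride = 1L,
                                  padding = if (side >= 5L) "valid" else "same"),
                             list(type = "relu")))
    side <- if (side >= 5L) out_side(side, 5L, 1L) else side
    layers <- add_pool(layers, side, "avg")
    layers <- c(layers, list(list(type = "flatten"),
                             list(type = "dense", units = 120L),
                             list(type = "relu"),
                             list(type = "dense", units = 84L),
                             list(type = "relu"),
                             list(type = "dense", units = n_classes)))
    return(model_spec(layers, input_shape, n_classes, "lenet"))
  }
  stop(sprintf("unknown baseline '%s' (expected 'cnn2d' or 'lenet')", name),
       call. = FALSE)
}

# ---- parameter initialization ----------------------------------------------

# class-stratified unit-norm kernel prototypes drawn from training windows:
# X is (n, s, s, D); the centered k x k window of each sampled patch becomes
# one kernel, cycling over classes so every class seeds some units
sample_prototypes <- function(X, y, k, n_units) {
  d <- dim(X)
  off <- (d[2L] - k) %/% 2L
  classes <- sort(unique(y))
  picks <- integer(n_units)
  by_class <- lapply(classes, function(cl) which(y == cl))
  for (u in seq_len(n_units)) {
    pool <- by_class[[(u - 1L) %% length(classes) + 1L]]
    picks[u] <- pool[sample.int(length(pool), 1L)]
  }
  W <- vapply(picks, function(i)
    as.vector(X[i, off + seq_len(k), off + seq_len(k), , drop = FALSE]),
    numeric(k * k * d[4L]))
  nrm <- sqrt(colSums(W^2))
  bad <- nrm < 1e-12
  if (any(bad)) {   # an all-zero window cannot serve as a direction
    W[, bad] <- stats::rnorm(sum(bad) * nrow(W))
    nrm <- sqrt(colSums(W^2))
  }
  sweep(W, 2L, nrm, "/")
}

init_params <- function(spec, seed, train_x = NULL, train_y = NULL) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  shape <- spec$input_shape           # (h, w, c) then flattened features
  n_layers <- length(spec$layers)
  params <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    ly <- spec$layers[[i]]
    params[[i]] <- switch(ly$type,
      scs = {
        m <- ly$kernel_size^2 * shape[3L]
        if (identical(ly$init %||% "prototype", "prototype") &&
            i == 1L && !is.null(train_x)) {
          W <- sample_prototypes(train_x, train_y, ly$kernel_size,
                                 ly$n_units)
        } else {
          # directions uniform on the unit sphere: SCS is scale-invariant
          # in w, so only the direction matters
          W <- matrix(stats::rnorm(m * ly$n_units), m, ly$n_units)
          W <- sweep(W, 2L, sqrt(colSums(W^2)), "/")
        }
        side <- out_side(shape[1L], ly$kernel_size, ly$stride)
        shape <- c(side, out_side(shape[2L], ly$kernel_size, ly$stride),
                    ly$n_units)
        list(W = W, q = rep(ly$q_init, ly$n_units),
             p = rep(ly$p_init, ly$n_units))
      },
      conv = {
        m <- ly$kernel_size^2 * shape[3L]
        W <- matrix(stats::rnorm(m * ly$filters, sd = sqrt(2 / m)),
                    m, ly$filters)
        if (ly$padding == "valid") {
          shape <- c(out_side(shape[1L], ly$kernel_size, ly$stride),
                      out_side(shape[2L], ly$kernel_size, ly$stride),
                      ly$filters)
        } else shape <- c(shape[1L], shape[2L], ly$filters)
        list(W = W, b = numeric(ly$filters))
      },
      pool = {
        shape <- c(out_side(shape[1L], ly$window, ly$stride),
                    out_side(shape[2L], ly$window, ly$stride), shape[3L])
        NULL
      },
      flatten = { shape <- prod(shape); NULL },
      dense = {
        f_in <- shape[1L]
        W <- matrix(stats::rnorm(f_in * ly$units, sd = sqrt(2 / f_in)),
                    f_in, ly$units)
        shape <- ly$units
        list(W = W, b = numeric(ly$units))
      },
      batchnorm = list(gamma = rep(1, shape[1L]), beta = numeric(shape[1L]),
                       run_mean = numeric(shape[1L]),
                       run_var = rep(1, shape[1L])),
      NULL)
  }
  params
}

# ---- forward / loss ---------------------------------------------------------

model_forward <- function(spec, params, x, training = FALSE) {
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    fb <- layer_forward(spec$layers[[i]], params[[i]], x, training)
    x <- fb$out
    caches[[i]] <- fb$cache
  }
  list(logits = x, caches = caches)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

softmax_xent <- function(logits, y) {
  n <- nrow(logits)
  probs <- softmax_rows(logits)
  eps <- 1e-12
  loss <- -mean(log(probs[cbind(seq_len(n), y)] + eps))
  dlogits <- probs
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p, function(a) list(m = a * 0, v = a * 0))
  })
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      params[[i]][[nm]] <- params[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

apply_constraints <- function(spec, params) {
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$type == "scs") {
      params[[i]]$q <- pmax(params[[i]]$q, ly$q_floor)
      params[[i]]$p <- pmax(params[[i]]$p, 1)
    }
  }
  params
}

# ---- training ---------------------------------------------------------------

eval_split <- function(spec, params, X, y) {
  if (length(y) == 0L) return(c(loss = NA_real_, acc = NA_real_))
  fw <- model_forward(spec, params, X, training = FALSE)
  sx <- softmax_xent(fw$logits, y)
  pred <- max.col(sx$probs, ties.method = "first")
  c(loss = sx$loss, acc = mean(pred == y))
}

#' Train a model on a patch set
#'
#' Minimizes softmax cross-entropy on the training split with minibatch Adam,
#' recording train and validation loss/accuracy every epoch. Deterministic
#' for a fixed `cfg$seed` (initialization and shuffling both derive from it).
#'
#' @param spec a `model_spec` from [build_scs_classifier()] or
#'   [build_baseline()].
#' @param pset a [patch_set].
#' @param split a `split_indices` from [stratified_split()].
#' @param cfg a [training_config()].
#' @return An object of class `trained_model` with elements `spec`, `params`,
#'   `history` (data frame: epoch, train_loss, train_acc, val_loss, val_acc),
#'   `config`, `class_names`.
#' @export
train_model <- function(spec, pset, split, cfg = training_config()) {
  if (!inherits(cfg, "training_config")) stop("`cfg` must be a training_config")
  idx <- split$train
  if (length(idx) == 0L) stop("empty train split", call. = FALSE)
  if (max(c(split$train, split$val, split$test)) > dim(pset$patches)[1L])
    stop("split indices exceed the patch set", call. = FALSE)
  y_tr <- pset$labels[idx]
  classes <- sort(unique(pset$labels))
  if (length(unique(y_tr)) < 2L)
    stop("training split contains a single class; cannot fit a classifier",
         call. = FALSE)
  if (!all(classes %in% y_tr))
    stop("every class needs at least one training sample", call. = FALSE)
  d <- dim(pset$patches)
  if (!identical(as.integer(d[2:4]), spec$input_shape))
    stop(sprintf("patch shape (%s) does not match model input (%s)",
                 paste(d[2:4], collapse = ","),
                 paste(spec$input_shape, collapse = ",")), call. = FALSE)

  X_tr <- pset$patches[idx, , , , drop = FALSE]
  X_val <- pset$patches[split$val, , , , drop = FALSE]
  y_val <- pset$labels[split$val]

  params <- init_params(spec, cfg$seed, train_x = X_tr, train_y = y_tr)
  state <- adam_init(params)
  n <- length(idx)
  t_step <- 0L
  hist <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                     train_acc = NA_real_, val_loss = NA_real_,
                     val_acc = NA_real_)
  set.seed((as.integer(cfg$seed) + 1L) %% .Machine$integer.max)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq.int(1L, n, by = cfg$batch_size)) {
      bi <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- X_tr[bi, , , , drop = FALSE]
      yb <- y_tr[bi]
      fw <- model_forward(spec, params, xb, training = TRUE)
      sx <- softmax_xent(fw$logits, yb)
      if (!is.finite(sx$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d", ep),
             call. = FALSE)
      ep_loss <- ep_loss + sx$loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(sx$probs, ties.method = "first") == yb)
      # backward
      dout <- sx$dlogits
      grads <- vector("list", length(spec$layers))
      for (i in rev(seq_along(spec$layers))) {
        bb <- layer_backward(spec$layers[[i]], params[[i]], fw$caches[[i]],
                             dout)
        grads[i] <- list(bb$grads)   # keep NULL slots for param-free layers
        dout <- bb$dx
      }
      # batchnorm running stats (momentum 0.9)
      for (i in seq_along(spec$layers)) {
        if (spec$layers[[i]]$type == "batchnorm") {
          cc <- fw$caches[[i]]
          params[[i]]$run_mean <- 0.9 * params[[i]]$run_mean + 0.1 * cc$mu
          params[[i]]$run_var <- 0.9 * params[[i]]$run_var + 0.1 * cc$var
        }
      }
      t_step <- t_step + 1L
      up <- adam_step(params, grads, state, cfg$learning_rate, t_step)
      params <- apply_constraints(spec, up$params)
      state <- up$state
    }
    vm <- eval_split(spec, params, X_val, y_val)
    hist$train_loss[ep] <- ep_loss / n
    hist$train_acc[ep] <- ep_correct / n
    hist$val_loss[ep] <- vm["loss"]
    hist$val_acc[ep] <- vm["acc"]
  }
  structure(list(spec = spec, params = params, history = hist, config = cfg,
                 class_names = pset$class_names),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<trained_model '%s'> %d epochs; final train acc %.3f, val acc %s\n",
    x$spec$name, nrow(x$history), last$train_acc,
    ifelse(is.na(last$val_acc), "NA", sprintf("%.3f", last$val_acc))))
  invisible(x)
}

#' Predict class labels and probabilities for patches
#'
#' @param model a `trained_model`.
#' @param patches a [patch_set] or a 4-D array (n, s, s, D).
#' @return List with `labels` (integer class codes) and `probs`
#'   (n x C matrix, rows summing to 1). Empty input yields empty output.
#' @export
predict_labels <- function(model, patches) {
  X <- if (inherits(patches, "patch_set")) patches$patches else patches
  if (is.null(dim(X)) || length(dim(X)) != 4L)
    stop("`patches` must be a patch_set or a (n, s, s, D) array",
         call. = FALSE)
  if (dim(X)[1L] == 0L)
    return(list(labels = integer(0),
                probs = matrix(0, 0L, model$spec$n_classes)))
  if (!identical(as.integer(dim(X)[2:4]), model$spec$input_shape))
    stop(sprintf("patch shape (%s) does not match model input (%s)",
                 paste(dim(X)[2:4], collapse = ","),
                 paste(model$spec$input_shape, collapse = ",")),
         call. = FALSE)
  fw <- model_forward(model$spec, model$params, X, training = FALSE)
  probs <- softmax_rows(fw$logits)
  list(labels = max.col(probs, ties.method = "first"), probs = probs)
}

#' Predict a full-scene classification map
#'
#' Extracts a patch at every pixel of the cube and assigns each pixel the
#' model's predicted class, producing a complete map like the pipeline's
#' rendered output.
#'
#' @param model a `trained_model`.
#' @param cube a [hyper_cube] whose band count matches the model input depth.
#' @param s patch side (must match the model input).
#' @param padding `"zero"` or `"mirror"`.
#' @param batch_size pixels scored per forward pass.
#' @return A [label_mask] of predicted classes over the full grid.
#' @export
predict_map <- function(model, cube, s = model$spec$input_shape[1L],
                        padding = "zero", batch_size = 4096L) {
  d <- dim(cube$data)
  if (d[3L] != model$spec$input_shape[3L])
    stop(sprintf("cube has %d bands but the model expects %d",
                 d[3L], model$spec$input_shape[3L]), call. = FALSE)
  dummy <- label_mask(matrix(0L, d[1L], d[2L]), model$class_names, 0L)
  pset <- extract_patches(cube, dummy, s = s, padding = padding,
                          all_pixels = TRUE)
  n <- dim(pset$patches)[1L]
  labels <- integer(n)
  for (start in seq.int(1L, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n)
    labels[sel] <- predict_labels(model,
      pset$patches[sel, , , , drop = FALSE])$labels
  }
  out <- matrix(0L, d[1L], d[2L])
  out[cbind(pset$coords[, 1L] + 1L, pset$coords[, 2L] + 1L)] <- labels
  label_mask(out, model$class_names, unlabeled_value = -1L)
}

#' Write a training history to CSV
#'
#' @param model a `trained_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(model, path) {
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}
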