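#' Sharpened Cosine Similarity score
#'
#' The SCS operator replaces the convolutional dot product between a kernel
#' `w` and an image window `x` with a magnitude-normalized similarity,
#'
#'   c = (w . x) / ((||w|| + q) (||x|| + q)),     SCS = sign(c) |c|^p,
#'
#' where `q >= 0` stabilizes the division for small-magnitude inputs and the
#' sign-preserving exponent `p >= 1` sharpens the response. With `q = 0,
#' p = 1` this is exactly classical cosine similarity, so the score always
#' lies in [-1, 1] for `p = 1`.
#'
#' The stabilizer is applied to the norms by default (`q_mode = "norm"`),
#' which preserves the cosine limit at q = 0; `q_mode = "component"` instead
#' adds q to every vector component before taking norms, the alternative
#' literal reading of the denominator.
#'
#' @param w,x numeric vectors of equal length (kernels and windows are
#'   flattened before scoring).
#' @param q non-negative stabilizer.
#' @param p sharpening exponent, >= 1.
#' @param q_mode `"norm"` (default) or `"component"`.
#' @return A single score; in [-1, 1] whenever p = 1.
#' @examples
#' scs_score(c(1, 2, 2), c(1, 2, 2))            # parallel: 1
#' scs_score(c(1, 0), c(0, 1))                  # orthogonal: 0
#' scs_score(c(3, 4), c(3, 4), q = 5)           # damped: 0.25
#' scs_score(c(3, 4), c(3, 4), q = 5, p = 2)    # sharpened: 0.0625
#' @export
scs_score <- function(w, x, q = 0, p = 1, q_mode = c("norm", "component")) {
  q_mode <- match.arg(q_mode)
  if (length(w) != length(x))
    stop("`w` and `x` must have equal length", call. = FALSE)
  if (q < 0) stop("`q` must be non-negative", call. = FALSE)
  if (p < 1) stop("`p` must be >= 1", call. = FALSE)
  if (q_mode == "component") {
    den <- sqrt(sum((w + q)^2)) * sqrt(sum((x + q)^2))
    if (den == 0)
      stop("undefined cosine: zero-magnitude vector with q = 0", call. = FALSE)
    cc <- sum(w * x) / den
  } else {
    nw <- sqrt(sum(w^2)); nx <- sqrt(sum(x^2))
    if (q == 0 && (nw == 0 || nx == 0))
      stop("undefined cosine: zero vector with q = 0", call. = FALSE)
    cc <- sum(w * x) / ((nw + q) * (nx + q))
  }
  sign(cc) * abs(cc)^p
}

#' SCS score with analytic gradients
#'
#' Evaluates [scs_score()] (norm-offset stabilizer) together with its exact
#' partial derivatives with respect to the kernel `w`, the stabilizer `q`,
#' and the exponent `p` — the quantities backpropagation needs. Writing
#' c = (w.x)/((||w||+q)(||x||+q)) and S = sign(c)|c|^p:
#' dS/dc = p |c|^(p-1), dc/dw = x/den - c w/(||w||(||w||+q)),
#' dc/dq = -c (1/(||w||+q) + 1/(||x||+q)), dS/dp = S log|c|.
#'
#' @inheritParams scs_score
#' @return List with `value`, `dw` (vector), `dq`, `dp`.
#' @export
scs_score_grad <- function(w, x, q = 0, p = 1) {
  if (length(w) != length(x))
    stop("`w` and `x` must have equal length", call. = FALSE)
  nw <- sqrt(sum(w^2)); nx <- sqrt(sum(x^2))
  if (q == 0 && (nw == 0 || nx == 0))
    stop("undefined cosine: zero vector with q = 0", call. = FALSE)
  den <- (nw + q) * (nx + q)
  dot <- sum(w * x)
  cc <- dot / den
  s <- sign(cc) * abs(cc)^p
  ds_dc <- p * abs(cc)^(p - 1)
  w_unit <- if (nw > 0) w / nw else numeric(length(w)) # dot = 0 when nw = 0
  dc_dw <- x / den - cc * w_unit / (nw + q)
  dc_dq <- -cc * (1 / (nw + q) + 1 / (nx + q))
  dp <- if (cc == 0) 0 else s * log(abs(cc))
  list(value = s, dw = ds_dc * dc_dw, dq = ds_dc * dc_dq, dp = dp)
}

# Vectorized SCS scoring of many windows against many kernels.
# Xcol: (n_windows x m) flattened windows; W: (m x U) flattened kernels;
# q, p: length-U (per-kernel). Returns n_windows x U score matrix.
scs_forward_matrix <- function(Xcol, W, q, p) {
  U <- ncol(W)
  q <- rep_len(q, U); p <- rep_len(p, U)
  xn <- sqrt(rowSums(Xcol^2))
  wn <- sqrt(colSums(W^2))
  den <- outer(xn, wn) + outer(xn, q) + outer(rep(1, length(xn)), wn * q + q^2)
  # den = (xn + q)(wn + q), expanded to keep outer() allocation-light
  cc <- (Xcol %*% W) / den
  pm <- matrix(p, nrow(cc), U, byrow = TRUE)
  sign(cc) * abs(cc)^pm
}

#' SCS kernel
#'
#' A single SCS unit: flattened weights with their window shape, a
#' non-negative stabilizer `q`, and a sharpening exponent `p`.
#'
#' @param w numeric array (k, k, D) or vector of kernel weights.
#' @param q non-negative stabilizer (default 0.1).
#' @param p sharpening exponent (default 1).
#' @return An object of class `scs_kernel`.
#' @export
scs_kernel <- function(w, q = 0.1, p = 1) {
  if (any(!is.finite(w))) stop("kernel weights must be finite", call. = FALSE)
  if (q < 0) stop("`q` must be non-negative", call. = FALSE)
  if (p < 1) stop("`p` must be >= 1", call. = FALSE)
  structure(list(w = w, q = q, p = p), class = "scs_kernel")
}

#' SCS layer configuration
#'
#' @param n_units number of kernels (default 32).
#' @param kernel_size window side k (default 3).
#' @param stride positive stride (default 1).
#' @param q_init,p_init initial stabilizer and sharpening exponent. The
#'   exponent starts at 2 — the conventional initialization for sharpened
#'   cosine layers, which widens the gap between strong and weak matches
#'   from the first epoch — and is trained from there; `p_init = 1` starts
#'   at the plain cosine operator instead.
#' @param q_trainable,p_trainable whether q and p are optimized during
#'   training; `q` is floored at `q_floor` during optimization to keep the
#'   denominator away from zero.
#' @param q_floor lower bound applied to q during training (default 1e-6).
#' @param q_mode `"norm"` or `"component"` (see [scs_score()]).
#' @param init kernel initialization: `"sphere"` (default; directions
#'   uniform on the unit sphere — only the direction matters since SCS is
#'   scale-invariant in w) or `"prototype"` (kernels start as
#'   unit-normalized windows sampled class-stratified from the training
#'   patches, i.e. matched filters against class exemplars).
#' @return An object of class `scs_layer_config`.
#' @export
scs_layer_config <- function(n_units = 32L, kernel_size = 3L, stride = 1L,
                             q_init = 0.1, p_init = 2.0,
                             q_trainable = TRUE, p_trainable = TRUE,
                             q_floor = 1e-6, q_mode = "norm",
                             init = c("sphere", "prototype")) {
  stopifnot(n_units >= 1L, kernel_size >= 1L, stride >= 1L, q_init >= 0,
            p_init >= 1, q_floor >= 0)
  structure(list(n_units = as.integer(n_units),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 q_init = q_init, p_init = p_init,
                 q_trainable = isTRUE(q_trainable),
                 p_trainable = isTRUE(p_trainable),
                 q_floor = q_floor,
                 q_mode = match.arg(q_mode, c("norm", "component")),
                 init = match.arg(init)),
            class = "scs_layer_config")
}

# flattened sliding windows of a (h, w, D) array: one row per output
# position in row-major order; columns in (dr, dc, channel) order with
# channel slowest (matching how kernels are flattened from (k, k, D)).
im2col <- function(input, k, stride) {
  d <- dim(input)
  h <- d[1L]; w <- d[2L]; D <- d[3L]
  ho <- (h - k) %/% stride + 1L
  wo <- (w - k) %/% stride + 1L
  out <- matrix(0, ho * wo, k * k * D)
  pos <- 0L
  for (r in seq_len(ho)) for (c in seq_len(wo)) {
    pos <- pos + 1L
    rs <- (r - 1L) * stride + seq_len(k)
    cs <- (c - 1L) * stride + seq_len(k)
    out[pos, ] <- as.vector(input[rs, cs, , drop = FALSE])
  }
  out
}

#' Forward pass of an SCS layer over a window stack
#'
#' Slides every kernel over the input at the configured stride, scoring each
#' k x k x D window with [scs_score()]. There is no bias, normalization, or
#' activation function; the raw similarity map is the layer output.
#'
#' @param input numeric array (h, w, D).
#' @param config an [scs_layer_config()].
#' @param kernels list of [scs_kernel()] objects, all of shape
#'   (kernel_size, kernel_size, D).
#' @return Feature map array (h', w', n_units), with
#'   h' = floor((h - k)/stride) + 1.
#' @export
scs_layer_forward <- function(input, config, kernels) {
  d <- dim(input)
  if (length(d) != 3L) stop("`input` must be (h, w, D)", call. = FALSE)
  k <- config$kernel_size
  if (k > min(d[1L], d[2L]))
    stop(sprintf("kernel size %d exceeds input spatial dims %d x %d",
                 k, d[1L], d[2L]), call. = FALSE)
  m <- k * k * d[3L]
  W <- matrix(0, m, length(kernels))
  q <- p <- numeric(length(kernels))
  for (u in seq_along(kernels)) {
    kw <- kernels[[u]]$w
    if (length(kw) != m)
      stop(sprintf("kernel %d has %d weights; expected %d x %d x %d = %d",
                   u, length(kw), k, k, d[3L], m), call. = FALSE)
    W[, u] <- as.vector(kw)
    q[u] <- kernels[[u]]$q
    p[u] <- kernels[[u]]$p
  }
  Xcol <- im2col(input, k, config$stride)
  scores <- scs_forward_matrix(Xcol, W, q, p)
  ho <- (d[1L] - k) %/% config$stride + 1L
  wo <- (d[2L] - k) %/% config$stride + 1L
  # scores rows are row-major positions; array() fills column-major
  array(aperm(array(scores, c(wo, ho, length(kernels))), c(2L, 1L, 3L)),
        c(ho, wo, length(kernels)))
}

#' Absolute max-pooling
#'
#' Standard max-pooling keeps the largest value in each window; SCS responses
#' are signed similarities, so pooling instead keeps the value of largest
#' magnitude irrespective of sign (a strong anti-match is as informative as a
#' strong match). Ties in magnitude are broken by the first occurrence in
#' row-major window order, making the operator deterministic.
#'
#' @param fmap numeric array (h, w, C) or matrix (h, w).
#' @param window pool window side.
#' @param stride stride; defaults to `window`.
#' @return Pooled array (h', w', C) with the signed selected values.
#' @examples
#' abs_max_pool(array(c(-5, 3, 2, -1), c(2, 2, 1)), 2)  # keeps -5
#' @export
abs_max_pool <- function(fmap, window, stride = window) {
  was_matrix <- is.matrix(fmap)
  if (was_matrix) fmap <- array(fmap, c(dim(fmap), 1L))
  d <- dim(fmap)
  window <- as.integer(window); stride <- as.integer(stride)
  if (window > min(d[1L], d[2L]))
    stop(sprintf("pool window %d exceeds spatial dims %d x %d",
                 window, d[1L], d[2L]), call. = FALSE)
  ho <- (d[1L] - window) %/% stride + 1L
  wo <- (d[2L] - window) %/% stride + 1L
  out <- array(0, c(ho, wo, d[3L]))
  for (ch in seq_len(d[3L])) for (r in seq_len(ho)) for (c in seq_len(wo)) {
    rs <- (r - 1L) * stride + seq_len(window)
    cs <- (c - 1L) * stride + seq_len(window)
    win <- fmap[rs, cs, ch]
    vals <- as.vector(t(win))       # row-major order for the tie rule
    out[r, c, ch] <- vals[which.max(abs(vals))]
  }
  if (was_matrix && d[3L] == 1L) matrix(out[, , 1L], ho, wo) else out
}
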