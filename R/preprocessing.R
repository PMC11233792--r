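#' Reduce spectral dimension by Factor Analysis
#'
#' Fits a Factor Analysis model on the (M*N) x B matrix of band-standardized
#' spectra and replaces the B bands with `n_factors` factor-score bands, each
#' rescaled to zero mean and unit variance over the scene. This is the
#' dimension-reduction step applied before patch extraction; the default
#' throughout the pipeline is 3 factors.
#'
#' Maximum-likelihood estimation (`stats::factanal`) is used when it
#' converges; scenes whose band covariance is nearly low-rank (uniquenesses
#' driven to the boundary) make the MLE fail, in which case a principal-axis
#' fit is used instead and a message is emitted. `mode = "select"` supports
#' the alternative reading of FA-based reduction in which the original band
#' with the largest absolute loading on each factor is kept unchanged.
#'
#' @param cube a [hyper_cube].
#' @param n_factors number of derived bands (default 3).
#' @param seed integer seed (the fit is deterministic; the seed pins any
#'   future stochastic refinement and is recorded with the output).
#' @param mode `"scores"` (factor-score bands, the default) or `"select"`
#'   (keep the original band with maximal absolute loading per factor).
#' @param method `"ml"`, `"principal"`, or `"auto"` (ml with principal-axis
#'   fallback).
#' @return A [hyper_cube] with `n_factors` bands; the loading matrix is
#'   attached as attribute `"loadings"` and the retained band indices (select
#'   mode) as `"selected_bands"`.
#' @export
reduce_bands_fa <- function(cube, n_factors = 3L, seed = 1L,
                            mode = c("scores", "select"),
                            method = c("auto", "ml", "principal")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  d <- dim(cube$data)
  B <- d[3L]
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L) stop("`n_factors` must be >= 1", call. = FALSE)
  if (n_factors > B)
    stop(sprintf("`n_factors` (%d) exceeds the number of bands (%d)",
                 n_factors, B), call. = FALSE)
  X <- matrix(cube$data, d[1L] * d[2L], B)
  sds <- apply(X, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep))
    stop("cube has zero variance in every band; no factors estimable",
         call. = FALSE)
  if (any(!keep))
    warning(sprintf("excluding %d zero-variance band(s) from standardization",
                    sum(!keep)), call. = FALSE)
  if (sum(keep) < n_factors)
    stop("fewer nonzero-variance bands than requested factors", call. = FALSE)
  Z <- scale(X[, keep, drop = FALSE])
  set.seed(as.integer(seed) %% .Machine$integer.max)

  fit <- NULL
  if (method %in% c("auto", "ml")) {
    fit <- tryCatch({
      fa <- stats::factanal(Z, factors = n_factors, scores = "regression",
                            rotation = "varimax")
      list(loadings = unclass(fa$loadings), scores = fa$scores)
    }, error = function(e) {
      if (method == "ml")
        stop(sprintf("maximum-likelihood factor analysis failed: %s",
                     conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fit) && method == "auto")
      message("ML factor analysis did not converge; using principal-axis fit")
  }
  if (is.null(fit)) fit <- fa_principal(Z, n_factors)

  L_full <- matrix(0, B, n_factors)
  L_full[keep, ] <- fit$loadings
  if (mode == "select") {
    sel <- integer(n_factors)
    pool <- which(keep)
    for (f in seq_len(n_factors)) {
      cand <- pool[order(-abs(fit$loadings[, f]))]
      sel[f] <- cand[!(cand %in% sel)][1L]  # distinct bands across factors
    }
    out <- cube$data[, , sel, drop = FALSE]
    res <- hyper_cube(out, band_centers = NULL,
                      name = sprintf("%s+fa%d-select", cube$name, n_factors))
    attr(res, "selected_bands") <- sel
  } else {
    S <- scale(fit$scores)           # unit variance over the scene
    res <- hyper_cube(array(S, dim = c(d[1L], d[2L], n_factors)),
                      band_centers = NULL,
                      name = sprintf("%s+fa%d", cube$name, n_factors))
  }
  attr(res, "loadings") <- L_full
  res
}

# Principal-axis factoring with squared-multiple-correlation priors;
# deterministic, tolerant of near-singular correlations.
fa_principal <- function(Z, k, iter = 50L, tol = 1e-6) {
  R <- stats::cor(Z)
  p <- ncol(R)
  Rr <- R + diag(1e-8, p)
  smc <- 1 - 1 / diag(solve(Rr))
  h2 <- pmin(pmax(smc, 1e-4), 0.999)
  for (it in seq_len(iter)) {
    Rh <- R
    diag(Rh) <- h2
    eg <- eigen(Rh, symmetric = TRUE)
    val <- pmax(eg$values[seq_len(k)], 0)
    L <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
    h2_new <- pmin(rowSums(L^2), 0.999)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
  }
  # fix sign: largest-magnitude loading positive per factor
  for (f in seq_len(k)) if (L[which.max(abs(L[, f])), f] < 0) L[, f] <- -L[, f]
  # regression scores on the fitted model, R_model = L L' + Psi, using the
  # Woodbury form R_model^-1 L = Psi^-1 L (I + L' Psi^-1 L)^-1; unlike
  # solve(cor(Z), L) this stays stable when the empirical correlation is
  # near-singular, tending to the least-squares subspace projection as the
  # uniquenesses shrink
  psi <- pmax(1 - h2, 0.005)
  PL <- L / psi
  scores <- Z %*% (PL %*% solve(diag(k) + crossprod(L, PL)))
  list(loadings = L, scores = scores)
}

#' Spectral-spatial patch set
#'
#' A set of s x s x D windows, each centered on a focal pixel and labeled by
#' that pixel's class. Constructed by [extract_patches()].
#'
#' @param patches 4-D array (n, s, s, D).
#' @param coords integer matrix (n, 2) of 0-based (row, col) focal pixels.
#' @param labels integer class per sample (1..C).
#' @param class_names character vector of class names.
#' @return An object of class `patch_set`.
#' @export
patch_set <- function(patches, coords, labels, class_names) {
  d <- dim(patches)
  stopifnot(length(d) == 4L, d[2L] == d[3L], d[1L] == nrow(coords),
            d[1L] == length(labels))
  structure(list(patches = patches, coords = coords,
                 labels = as.integer(labels),
                 class_names = as.character(class_names),
                 s = d[2L], D = d[4L]),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d samples, %d x %d x %d, classes: %s\n",
              dim(x$patches)[1L], x$s, x$s, x$D,
              paste(x$class_names, collapse = ", ")))
  invisible(x)
}

reflect_index <- function(i, n) {
  # reflect about the edge pixels (1 and n) without repeating them
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j >= n, period - j, j) + 1L
}

#' Extract spectral-spatial patches
#'
#' Builds one s x s x D window per labeled pixel (or per pixel, in full-scene
#' mode), centered on the focal pixel; the sample label is the focal pixel's
#' class. Positions falling outside the grid are filled by the padding rule.
#' Samples are ordered row-major by focal pixel.
#'
#' @param cube a [hyper_cube] (typically after [reduce_bands_fa()]).
#' @param mask a [label_mask] on the same grid; ignored when
#'   `all_pixels = TRUE` except for class names.
#' @param s odd patch side (default 3).
#' @param padding `"zero"` or `"mirror"`.
#' @param all_pixels if `TRUE`, extract a patch at every pixel (for
#'   whole-scene map prediction); unlabeled focal pixels get label 0.
#' @return A [patch_set].
#' @export
extract_patches <- function(cube, mask, s = 3L, padding = c("zero", "mirror"),
                            all_pixels = FALSE) {
  padding <- match.arg(padding)
  check_pair(cube, mask)
  s <- as.integer(s)
  if (s < 1L || s %% 2L == 0L)
    stop("`s` must be a positive odd integer (focal pixel centered)",
         call. = FALSE)
  d <- dim(cube$data)
  M <- d[1L]; N <- d[2L]; D <- d[3L]
  h <- (s - 1L) %/% 2L

  if (all_pixels) {
    ij <- cbind(rep(seq_len(M), times = N), rep(seq_len(N), each = M))
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
  } else {
    sel <- which(mask$labels != mask$unlabeled_value, arr.ind = TRUE)
    if (nrow(sel) == 0L)
      stop("mask has no labeled pixels; nothing to extract", call. = FALSE)
    ij <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
  }
  n <- nrow(ij)

  # pad once, then gather windows by index arithmetic
  if (padding == "zero") {
    big <- array(0, dim = c(M + 2L * h, N + 2L * h, D))
    big[h + seq_len(M), h + seq_len(N), ] <- cube$data
  } else {
    ridx <- reflect_index(seq.int(1L - h, M + h), M)
    cidx <- reflect_index(seq.int(1L - h, N + h), N)
    big <- cube$data[ridx, cidx, , drop = FALSE]
  }
  patches <- array(0, dim = c(n, s, s, D))
  flat <- matrix(big, (M + 2L * h) * (N + 2L * h), D)
  for (dr in seq_len(s)) for (dc in seq_len(s)) {
    rows <- ij[, 1L] + dr - 1L   # index into padded array
    cols <- ij[, 2L] + dc - 1L
    patches[, dr, dc, ] <- flat[rows + (cols - 1L) * (M + 2L * h), ]
  }
  labels <- mask$labels[ij]
  patch_set(patches, coords = cbind(row = ij[, 1L] - 1L, col = ij[, 2L] - 1L),
            labels = labels, class_names = mask$class_names)
}

#' Stratified per-class train/validation/test split
#'
#' Partitions the samples of a [patch_set] class by class at the given
#' fractions (default 15/15/70), using largest-remainder rounding within each
#' class so per-class counts are within one sample of the exact fractions.
#' Classes are processed in increasing code order and remainder ties go to
#' train, then validation, then test, making the split deterministic for a
#' fixed seed.
#'
#' @param x a [patch_set], or an integer label vector.
#' @param fractions numeric triple (train, val, test) summing to 1.
#' @param seed integer seed.
#' @param strict if `TRUE`, a class with fewer than 3 samples is an error;
#'   the default assigns all its samples to train with a warning.
#' @return An object of class `split_indices` with disjoint, exhaustive
#'   integer index vectors `train`, `val`, `test`.
#' @export
stratified_split <- function(x, fractions = c(0.15, 0.15, 0.70), seed = 1L,
                             strict = FALSE) {
  labels <- if (inherits(x, "patch_set")) x$labels else as.integer(x)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be a non-negative triple summing to 1",
         call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  train <- val <- test <- integer(0)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    n <- length(idx)
    if (n < 3L) {
      if (strict)
        stop(sprintf("class %d has only %d sample(s); cannot appear in all splits",
                     cls, n), call. = FALSE)
      warning(sprintf("class %d has only %d sample(s); assigning all to train",
                      cls, n), call. = FALSE)
      train <- c(train, idx)
      next
    }
    idx <- idx[sample.int(n)]
    counts <- largest_remainder(n, fractions)
    train <- c(train, idx[seq_len(counts[1L])])
    val <- c(val, idx[counts[1L] + seq_len(counts[2L])])
    test <- c(test, idx[counts[1L] + counts[2L] + seq_len(counts[3L])])
  }
  structure(list(train = train, val = val, test = test,
                 fractions = fractions, seed = as.integer(seed)),
            class = "split_indices")
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    # ties broken by position: train, then val, then test
    give <- order(-rem, seq_along(rem))[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' @export
print.split_indices <- function(x, ...) {
  cat(sprintf("<split_indices> train %d / val %d / test %d (fractions %s, seed %d)\n",
              length(x$train), length(x$val), length(x$test),
              paste(x$fractions, collapse = "/"), x$seed))
  invisible(x)
}

#' Subset a patch set by sample index
#'
#' @param pset a [patch_set].
#' @param idx integer sample indices.
#' @return A [patch_set] with the selected samples.
#' @export
subset_patches <- function(pset, idx) {
  patch_set(pset$patches[idx, , , , drop = FALSE],
            pset$coords[idx, , drop = FALSE],
            pset$labels[idx], pset$class_names)
}
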