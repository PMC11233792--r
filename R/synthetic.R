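# Synthetic labeled tissue scenes.
#
# Emulates the structure of intraoperative tissue cubes: four classes
# (normal tissue, tumor, blood vessel, background) with smooth distinct
# spectra, spatially contiguous regions (a background frame around the
# scene, an elliptical tumor blob inside normal tissue, a curvilinear vessel
# track), band-correlated additive noise, and partial labeling.

SCENE_CLASSES <- c("normal", "tumor", "vessel", "background")

#' Build a spectral library of class-mean signatures
#'
#' Each class mean is a smooth non-negative spectrum over band index — a
#' baseline plus 1 to 3 Gaussian bumps with class-specific centers and
#' widths. Within-class variation is band-correlated Gaussian noise with
#' marginal standard deviation `sigma` (correlation induced by a Gaussian
#' smoothing kernel of length scale about B/15 bands).
#'
#' `separation` is the knob controlling problem difficulty and is measured
#' in noise units along the discriminating direction: for each class pair
#' the Mahalanobis-like ratio of the mean difference to the noise standard
#' deviation projected on that difference,
#' d(i, j) = ||mu_i - mu_j||^2 / sqrt((mu_i - mu_j)' Sigma (mu_i - mu_j))
#' with Sigma the noise covariance. Because the noise is band-correlated,
#' it carries more variance along smooth (class-contrast) directions than
#' the marginal `sigma` suggests; projecting onto the contrast makes
#' `separation = 10` mean what it should — a pairwise Bayes error around
#' pnorm(-5) for the hardest class pair. After generation the class-mean
#' contrasts are rescaled so the minimum pairwise separation in this metric
#' equals the request.
#'
#' @param C number of classes (>= 2).
#' @param B number of bands (>= 3).
#' @param separation requested minimum pairwise mean separation, in units of
#'   sigma.
#' @param sigma marginal noise standard deviation per band.
#' @param seed integer seed; the library is a deterministic function of the
#'   arguments.
#' @return An object of class `spectral_library` with `class_means` (C x B),
#'   `sigma`, `smooth` (B x B noise-coloring matrix), `separation`
#'   (realized), `seed`.
#' @export
make_spectral_library <- function(C = 4L, B = 30L, separation = 10,
                                  sigma = 0.02, seed = 1L) {
  C <- as.integer(C); B <- as.integer(B)
  if (C < 2L) stop("need at least 2 classes", call. = FALSE)
  if (B < 3L) stop("need at least 3 bands", call. = FALSE)
  if (separation <= 0) stop("`separation` must be positive", call. = FALSE)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  bands <- seq_len(B)
  means <- matrix(0, C, B)
  for (cl in seq_len(C)) {
    nb <- sample(1:3, 1L)
    spec <- rep(0.3, B)
    for (b in seq_len(nb)) {
      center <- stats::runif(1L, 0.1, 0.9) * B
      width <- stats::runif(1L, 0.08, 0.25) * B
      height <- stats::runif(1L, 0.2, 0.8)
      spec <- spec + height * exp(-0.5 * ((bands - center) / width)^2)
    }
    means[cl, ] <- spec
  }
  # noise-coloring matrix: Gaussian kernel rows, unit l2 norm so the
  # marginal per-band standard deviation is exactly sigma
  ell <- max(1, B / 15)
  K <- exp(-0.5 * (outer(bands, bands, "-") / ell)^2)
  K <- K / sqrt(rowSums(K^2))
  dmin <- min_separation(means, K, sigma)
  if (!is.finite(dmin) || dmin < 1e-9)
    stop("degenerate library: coincident class means; change the seed",
         call. = FALSE)
  grand <- colMeans(means)
  dev <- sweep(means, 2L, grand)
  # projected-direction separation is linear in the mean contrasts, so one
  # rescale hits the target exactly
  means <- sweep(dev * (separation / dmin), 2L, grand, "+")
  means <- means - min(means) + 0.05          # keep spectra non-negative
  realized <- min_separation(means, K, sigma)
  structure(list(class_means = means, sigma = sigma, smooth = K,
                 separation = realized, seed = as.integer(seed),
                 C = C, B = B),
            class = "spectral_library")
}

# minimum pairwise separation of class means in projected noise units:
# ||d||^2 / sqrt(d' Sigma d), Sigma = sigma^2 K K' (noise covariance)
min_separation <- function(means, K, sigma) {
  C <- nrow(means)
  dmin <- Inf
  for (i in seq_len(C - 1L)) for (j in seq.int(i + 1L, C)) {
    d <- means[i, ] - means[j, ]
    proj_sd <- sigma * sqrt(sum(crossprod(K, d)^2)) # ||d|| * noise sd along d
    dmin <- min(dmin, sum(d * d) / proj_sd)
  }
  dmin
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf(
    "<spectral_library> %d classes x %d bands, sigma %.3g, min separation %.2f sigma\n",
    x$C, x$B, x$sigma, x$separation))
  invisible(x)
}

#' Scene layout and sampling specification
#'
#' @param M,N grid dimensions (>= 16 each).
#' @param B number of bands.
#' @param labeled_fraction share of pixels per class carrying ground-truth
#'   labels (the rest are unlabeled, as in partially annotated surgical
#'   scenes).
#' @param seed integer seed for labeling and noise.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(M = 64L, N = 64L, B = 30L, labeled_fraction = 0.5,
                       seed = 1L) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 16L || N < 16L)
    stop("scene must be at least 16 x 16 to fit the class layout",
         call. = FALSE)
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("`labeled_fraction` must be in (0, 1]", call. = FALSE)
  structure(list(M = M, N = N, B = as.integer(B),
                 labeled_fraction = labeled_fraction,
                 seed = as.integer(seed), class_names = SCENE_CLASSES),
            class = "scene_spec")
}

# deterministic class layout: background frame, normal interior, elliptical
# tumor blob, sinusoidal vessel track
scene_layout <- function(M, N) {
  layout <- matrix(1L, M, N)                       # normal tissue
  frame <- max(3L, round(min(M, N) * 0.09))
  layout[c(seq_len(frame), M - seq_len(frame) + 1L), ] <- 4L
  layout[, c(seq_len(frame), N - seq_len(frame) + 1L)] <- 4L
  rr <- matrix(seq_len(M), M, N)
  cc <- matrix(seq_len(N), M, N, byrow = TRUE)
  # tumor: rotated ellipse placed off-center in the tissue interior
  cr <- M * 0.42; ccol <- N * 0.58
  a <- (M - 2 * frame) / 5.2; b <- (N - 2 * frame) / 6.5
  th <- pi / 7
  u <- (rr - cr) * cos(th) + (cc - ccol) * sin(th)
  v <- -(rr - cr) * sin(th) + (cc - ccol) * cos(th)
  tumor <- (u / a)^2 + (v / b)^2 <= 1 & layout == 1L
  layout[tumor] <- 2L
  # vessel: sinusoidal track of ~2 px half-width through the interior
  track <- M * 0.68 + 0.12 * M * sin(2 * pi * (seq_len(N) / N) * 1.7 + 0.6)
  vessel <- abs(rr - matrix(track, M, N, byrow = TRUE)) <= 1.2 &
    layout == 1L
  layout[vessel] <- 3L
  if (!all(1:4 %in% layout))
    stop("scene too small: a class received no pixels", call. = FALSE)
  layout
}

#' Generate a labeled synthetic tissue scene
#'
#' Lays out the four tissue classes, draws every pixel's spectrum as its
#' class mean plus band-correlated Gaussian noise, and labels a per-class
#' random subset of pixels at the spec's `labeled_fraction` (the remainder
#' are unlabeled). Bit-identical output for a fixed spec and library.
#'
#' @param spec a [scene_spec()].
#' @param library a [make_spectral_library()] result with `C = 4` classes
#'   and `B` matching the spec.
#' @param noise_sd marginal noise level; defaults to the library's `sigma`.
#'   `0` produces exact class-mean spectra.
#' @return List with `cube` (a [hyper_cube]), `mask` (a [label_mask] with
#'   unlabeled code 0), and `truth` (a fully labeled [label_mask]).
#' @export
generate_scene <- function(spec, library, noise_sd = NULL) {
  if (!inherits(spec, "scene_spec")) stop("`spec` must be a scene_spec")
  if (!inherits(library, "spectral_library"))
    stop("`library` must be a spectral_library")
  if (library$C != length(spec$class_names))
    stop(sprintf("library has %d classes; scene layout needs %d",
                 library$C, length(spec$class_names)), call. = FALSE)
  if (library$B != spec$B)
    stop(sprintf("library has %d bands; spec declares %d",
                 library$B, spec$B), call. = FALSE)
  if (is.null(noise_sd)) noise_sd <- library$sigma
  M <- spec$M; N <- spec$N; B <- spec$B
  layout <- scene_layout(M, N)
  set.seed(spec$seed %% .Machine$integer.max)
  X <- library$class_means[as.vector(layout), , drop = FALSE]  # (M*N) x B
  if (noise_sd > 0) {
    E <- matrix(stats::rnorm(M * N * B), M * N, B) %*% t(library$smooth)
    X <- X + noise_sd * E
  }
  X <- pmax(X, 0)
  cube <- hyper_cube(array(X, c(M, N, B)),
                     name = sprintf("synthetic-%dx%dx%d-seed%d",
                                    M, N, B, spec$seed))
  labels <- matrix(0L, M, N)
  for (cl in seq_len(library$C)) {
    pix <- which(layout == cl)
    n_lab <- round(length(pix) * spec$labeled_fraction)
    if (n_lab > 0L) {
      keep <- if (n_lab >= length(pix)) pix else sample(pix, n_lab)
      labels[keep] <- cl
    }
  }
  list(cube = cube,
       mask = label_mask(labels, spec$class_names, 0L),
       truth = label_mask(layout, spec$class_names, 0L))
}
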