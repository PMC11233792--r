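test_that("factor reduction returns the requested number of scaled bands", {
  cube <- random_cube(10, 10, 8, seed = 1)
  red <- suppressMessages(reduce_bands_fa(cube, 3, seed = 1))
  expect_equal(dim(red$data)[3], 3)
  scores <- matrix(red$data, 100, 3)
  expect_equal(colMeans(scores), rep(0, 3), tolerance = 1e-8)
  expect_equal(apply(scores, 2, sd), rep(1, 3), tolerance = 1e-8)
})

test_that("an exact 2-factor cube is reconstructed to >= 99% of variance", {
  # oracle: build data from a known 2-factor linear model, then measure the
  # reconstruction residual of the fitted loadings/scores directly
  set.seed(42)
  n <- 400; B <- 10
  F2 <- matrix(rnorm(n * 2), n, 2)
  L2 <- matrix(runif(B * 2, -1, 1), B, 2)
  X <- F2 %*% t(L2) + matrix(rnorm(n * B, sd = 0.01), n, B)
  cube <- hyper_cube(array(X, c(20, 20, B)))
  red <- suppressMessages(reduce_bands_fa(cube, 2, seed = 1))
  S <- matrix(red$data, n, 2)
  Z <- scale(matrix(cube$data, n, B))
  # project standardized data on the recovered score space
  fitted <- S %*% solve(crossprod(S), crossprod(S, Z))
  captured <- 1 - sum((Z - fitted)^2) / sum(Z^2)
  expect_gte(captured, 0.99)
})

test_that("degenerate cubes are rejected", {
  flat <- hyper_cube(array(1, c(5, 5, 4)))
  expect_error(suppressWarnings(reduce_bands_fa(flat, 2)), "zero variance")
  cube <- random_cube(5, 5, 4)
  expect_error(reduce_bands_fa(cube, 9), "exceeds")
})

test_that("factor scores are invariant to band-wise affine rescaling", {
  cube <- random_cube(12, 12, 8, seed = 9)
  set.seed(3)
  scl <- runif(8, 0.5, 5); off <- rnorm(8)
  rescaled <- cube
  for (b in 1:8) rescaled$data[, , b] <- cube$data[, , b] * scl[b] + off[b]
  a <- suppressMessages(reduce_bands_fa(cube, 3, seed = 1))
  b <- suppressMessages(reduce_bands_fa(rescaled, 3, seed = 1))
  # factors may flip sign or swap; match by maximal absolute correlation
  cors <- abs(cor(matrix(a$data, 144, 3), matrix(b$data, 144, 3)))
  expect_true(all(apply(cors, 1, max) >= 0.999))
})

test_that("band-selection mode returns original bands", {
  cube <- random_cube(10, 10, 8, seed = 2)
  sel <- suppressMessages(reduce_bands_fa(cube, 3, seed = 1, mode = "select"))
  bands <- attr(sel, "selected_bands")
  expect_length(unique(bands), 3)
  for (f in 1:3)
    expect_identical(sel$data[, , f], cube$data[, , bands[f]])
})

test_that("patch at a corner is zero-padded with the focal spectrum centered", {
  cube <- random_cube(5, 5, 2, seed = 7)
  labels <- matrix(0L, 5, 5); labels[1, 1] <- 1L
  mask <- label_mask(labels, c("a", "b"))
  ps <- extract_patches(cube, mask, 3, padding = "zero")
  expect_equal(dim(ps$patches), c(1, 3, 3, 2))
  expect_equal(ps$patches[1, 1, , ], matrix(0, 3, 2))   # padded row
  expect_equal(ps$patches[1, , 1, ], matrix(0, 3, 2))   # padded col
  expect_equal(ps$patches[1, 2, 2, ], cube$data[1, 1, ])
  expect_equal(ps$coords[1, ], c(row = 0, col = 0))
})

test_that("sample count equals labeled pixels regardless of class mix", {
  cube <- random_cube(6, 6, 3, seed = 1)
  set.seed(5)
  labels <- matrix(0L, 6, 6)
  labels[sample(36, 17)] <- sample(1:4, 17, replace = TRUE)
  mask <- label_mask(labels, c("a", "b", "c", "d"))
  ps <- extract_patches(cube, mask, 3)
  expect_equal(dim(ps$patches)[1], 17)
})

test_that("s = 1 patches equal the focal spectra exactly", {
  cube <- random_cube(6, 6, 4, seed = 2)
  mask <- random_mask(6, 6, seed = 2)
  ps <- extract_patches(cube, mask, 1)
  for (i in seq_len(min(5, dim(ps$patches)[1]))) {
    rc <- ps$coords[i, ] + 1L
    expect_equal(ps$patches[i, 1, 1, ], cube$data[rc[1], rc[2], ])
  }
})

test_that("patch centers always reproduce the original spectra", {
  cube <- random_cube(7, 8, 3, seed = 11)
  mask <- random_mask(7, 8, seed = 11)
  for (pad in c("zero", "mirror")) {
    ps <- extract_patches(cube, mask, 3, padding = pad)
    ctr <- ps$patches[, 2, 2, ]
    truth <- t(vapply(seq_len(nrow(ps$coords)), function(i)
      cube$data[ps$coords[i, 1] + 1, ps$coords[i, 2] + 1, ], numeric(3)))
    expect_equal(ctr, truth, label = pad)
  }
})

test_that("patch extraction rejects bad inputs", {
  cube <- random_cube(5, 5, 2)
  mask <- random_mask(5, 5)
  expect_error(extract_patches(cube, mask, 2), "odd")
  empty <- label_mask(matrix(0L, 5, 5), c("a", "b"))
  expect_error(extract_patches(cube, empty, 3), "no labeled")
})

test_that("15/15/70 split is exact for balanced 100-sample classes", {
  labels <- rep(1:4, each = 100)
  sp <- stratified_split(labels, c(0.15, 0.15, 0.70), seed = 1)
  for (cl in 1:4) {
    expect_equal(sum(labels[sp$train] == cl), 15)
    expect_equal(sum(labels[sp$val] == cl), 15)
    expect_equal(sum(labels[sp$test] == cl), 70)
  }
})

test_that("largest-remainder rounding gives (1,1,5) for a 7-sample class", {
  sp <- stratified_split(rep(1L, 7), c(0.15, 0.15, 0.70), seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 1L, val = 1L, test = 5L))
})

test_that("splits are deterministic, disjoint, and exhaustive", {
  set.seed(99)
  for (rep in 1:5) {
    labels <- sample(1:4, 50 + rep * 37, replace = TRUE,
                     prob = runif(4) + 0.2)
    a <- stratified_split(labels, seed = 7)
    b <- stratified_split(labels, seed = 7)
    expect_identical(a, b)
    all_idx <- c(a$train, a$val, a$test)
    expect_equal(sort(all_idx), seq_along(labels))
    expect_equal(anyDuplicated(all_idx), 0L)
  }
})

test_that("undersized classes go to train with a warning, or error in strict mode", {
  labels <- c(rep(1L, 20), 2L, 2L)
  expect_warning(sp <- stratified_split(labels, seed = 1), "assigning all")
  expect_true(all(which(labels == 2L) %in% sp$train))
  expect_error(stratified_split(labels, seed = 1, strict = TRUE), "class 2")
})
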