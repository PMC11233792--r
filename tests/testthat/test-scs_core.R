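test_that("scs_score matches hand-computed worked cases", {
  expect_equal(scs_score(c(1, 2, 2), c(1, 2, 2)), 1.0)
  expect_equal(scs_score(c(1, 0), c(0, 1)), 0.0)
  # ||w|| = ||x|| = 5, so c = 25 / ((5+5)(5+5)) = 0.25
  expect_equal(scs_score(c(3, 4), c(3, 4), q = 5), 0.25)
  expect_equal(scs_score(c(3, 4), c(3, 4), q = 5, p = 2), 0.0625)
})

test_that("zero vectors with q = 0 raise an undefined-cosine error", {
  expect_error(scs_score(c(0, 0), c(1, 1)), "zero vector")
  expect_no_error(scs_score(c(0, 0), c(1, 1), q = 0.1))
})

test_that("q = 0, p = 1 reduces exactly to cosine similarity", {
  set.seed(10)
  for (i in 1:200) {
    w <- rnorm(sample(2:20, 1)); x <- rnorm(length(w))
    expect_equal(scs_score(w, x), cosine_oracle(w, x), tolerance = 1e-12)
  }
})

test_that("score magnitude never exceeds 1 for p = 1 and any q >= 0", {
  set.seed(11)
  for (i in 1:200) {
    w <- rnorm(8) * 10^runif(1, -3, 3)
    x <- rnorm(8) * 10^runif(1, -3, 3)
    q <- runif(1, 0, 5)
    expect_lte(abs(scs_score(w, x, q = q)), 1)
  }
})

test_that("scaling either vector only affects the sign (q = 0, p = 1)", {
  set.seed(12)
  for (i in 1:50) {
    w <- rnorm(6); x <- rnorm(6)
    a <- runif(1, -4, 4); b <- runif(1, -4, 4)
    if (abs(a) < 1e-3 || abs(b) < 1e-3) next
    expect_equal(scs_score(a * w, b * x),
                 sign(a * b) * scs_score(w, x), tolerance = 1e-12)
  }
})

test_that("positive scores are non-increasing in q", {
  set.seed(13)
  for (i in 1:50) {
    w <- rnorm(5); x <- w + rnorm(5, sd = 0.3)   # mostly aligned pair
    s <- vapply(c(0, 0.5, 1, 2, 5), function(q) scs_score(w, x, q = q),
                numeric(1))
    if (s[1] > 0) expect_true(all(diff(s) <= 1e-12))
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(14)
  eps <- 1e-6
  for (i in 1:30) {
    n <- sample(3:12, 1)
    w <- rnorm(n); x <- rnorm(n)
    q <- runif(1, 0.01, 1); p <- runif(1, 1, 3)
    if (abs(cosine_oracle(w, x)) < 0.05) next   # away from c = 0
    g <- scs_score_grad(w, x, q, p)
    fd_w <- vapply(seq_len(n), function(j) {
      wp <- w; wp[j] <- wp[j] + eps
      wm <- w; wm[j] <- wm[j] - eps
      (scs_score(wp, x, q, p) - scs_score(wm, x, q, p)) / (2 * eps)
    }, numeric(1))
    expect_equal(g$dw, fd_w, tolerance = 1e-5)
    fd_q <- (scs_score(w, x, q + eps, p) - scs_score(w, x, q - eps, p)) /
      (2 * eps)
    expect_equal(g$dq, fd_q, tolerance = 1e-5)
    fd_p <- (scs_score(w, x, q, p + eps) - scs_score(w, x, q, p - eps)) /
      (2 * eps)
    expect_equal(g$dp, fd_p, tolerance = 1e-5)
  }
})

test_that("layer forward equals a brute-force loop over positions and kernels", {
  set.seed(15)
  input <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  kernels <- lapply(1:4, function(u)
    scs_kernel(array(rnorm(27), c(3, 3, 3)), q = runif(1, 0, 0.5),
               p = runif(1, 1, 2)))
  for (stride in 1:2) {
    cfg <- scs_layer_config(n_units = 4, kernel_size = 3, stride = stride)
    fm <- scs_layer_forward(input, cfg, kernels)
    side <- (6 - 3) %/% stride + 1
    expect_equal(dim(fm), c(side, side, 4))
    for (r in seq_len(side)) for (c in seq_len(side)) for (u in 1:4) {
      rs <- (r - 1) * stride + 1:3
      cs <- (c - 1) * stride + 1:3
      expect_equal(fm[r, c, u],
                   scs_score(as.vector(kernels[[u]]$w),
                             as.vector(input[rs, cs, ]),
                             q = kernels[[u]]$q, p = kernels[[u]]$p),
                   tolerance = 1e-12)
    }
  }
})

test_that("a 3x3 input with 32 kernels yields a 1x1x32 map; matching kernel scores 1", {
  set.seed(16)
  input <- array(rnorm(27), c(3, 3, 3))
  kernels <- lapply(1:32, function(u) scs_kernel(array(rnorm(27), c(3, 3, 3)),
                                                 q = 0, p = 1))
  kernels[[7]] <- scs_kernel(input, q = 0, p = 1)   # kernel equals the window
  cfg <- scs_layer_config(n_units = 32, kernel_size = 3, q_init = 0)
  fm <- scs_layer_forward(input, cfg, kernels)
  expect_equal(dim(fm), c(1, 1, 32))
  expect_equal(fm[1, 1, 7], 1.0)
})

test_that("kernel shape mismatches are named in the error", {
  input <- array(rnorm(3 * 3 * 3), c(3, 3, 3))
  cfg <- scs_layer_config(n_units = 1, kernel_size = 3)
  expect_error(scs_layer_forward(input, cfg, list(scs_kernel(rnorm(12)))),
               "expected 3 x 3 x 3")
  big <- scs_layer_config(n_units = 1, kernel_size = 5)
  expect_error(scs_layer_forward(input, big, list(scs_kernel(rnorm(75)))),
               "exceeds input")
})

test_that("absolute max-pooling keeps the largest magnitude with its sign", {
  expect_equal(abs_max_pool(matrix(c(-5, 2, 3, -1), 2, 2), 2)[1, 1], -5)
  expect_equal(abs_max_pool(matrix(2, 2, 2), 2)[1, 1], 2)
  # [[1, -2], [0, 2]]: |-2| == |2|, row-major scan meets -2 first
  tie <- matrix(c(1, 0, -2, 2), 2, 2)
  expect_equal(abs_max_pool(tie, 2)[1, 1], -2)
})

test_that("pooling equals a brute-force |.|-argmax scan on random maps", {
  set.seed(17)
  fmap <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  fmap[abs(fmap) < 0.2] <- 0   # inject exact ties
  for (window in 2:3) {
    pooled <- abs_max_pool(fmap, window, stride = window)
    for (ch in 1:2) for (r in seq_len(dim(pooled)[1]))
      for (c in seq_len(dim(pooled)[2])) {
        rs <- (r - 1) * window + seq_len(window)
        cs <- (c - 1) * window + seq_len(window)
        vals <- as.vector(t(fmap[rs, cs, ch]))   # row-major
        expect_equal(pooled[r, c, ch], vals[which.max(abs(vals))])
      }
  }
  expect_error(abs_max_pool(matrix(1, 2, 2), 3), "exceeds spatial")
})
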