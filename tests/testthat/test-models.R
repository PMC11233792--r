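# two-class separable patch set: constant class spectra 10 noise-sd apart
separable_patches <- function(n_per_class = 60, s = 3, D = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(1:2, each = n_per_class)
  means <- rbind(c(1, -1, 0.5), c(-1, 1, -0.5)) * 5
  patches <- array(0, c(n, s, s, D))
  for (i in seq_len(n))
    patches[i, , , ] <- array(rep(means[labels[i], ], each = s * s),
                              c(s, s, D)) + rnorm(s * s * D, sd = 0.5)
  patch_set(patches, cbind(row = seq_len(n) - 1L, col = 0L), labels,
            c("a", "b"))
}

test_that("the SCS classifier has the declared composition and parameter count", {
  spec <- build_scs_classifier(c(3, 3, 3), 4)
  types <- vapply(spec$layers, function(l) l$type, "")
  expect_equal(types, c("scs", "identity", "flatten", "dense"))
  params <- scsmap:::init_params(spec, 1)
  n_par <- length(params[[1]]$W) + length(params[[1]]$q) +
    length(params[[1]]$p) + length(params[[4]]$W) + length(params[[4]]$b)
  expect_equal(n_par, 32 * 27 + 32 * 2 + 32 * 4 + 4)
})

test_that("larger patches get a real absolute max-pooling stage", {
  spec <- build_scs_classifier(c(7, 7, 3), 4)
  types <- vapply(spec$layers, function(l) l$type, "")
  expect_equal(types, c("scs", "pool", "flatten", "dense"))
  expect_equal(spec$layers[[2]]$kind, "absmax")
})

test_that("single-pixel patches degenerate to per-spectrum scoring", {
  spec <- build_scs_classifier(c(1, 1, 5), 3)
  expect_equal(spec$layers[[1]]$kernel_size, 1)
})

test_that("classification requires at least two classes", {
  expect_error(build_scs_classifier(c(3, 3, 3), 1), "2 classes")
  expect_error(build_baseline("cnn2d", c(3, 3, 3), 1), "2 classes")
})

test_that("baseline architectures match their descriptions", {
  spec <- build_baseline("cnn2d", c(3, 3, 3), 4)
  types <- vapply(spec$layers, function(l) l$type, "")
  expect_equal(types, c("conv", "relu", "identity", "flatten", "dense",
                        "batchnorm", "relu", "dense"))
  expect_equal(spec$layers[[1]]$kernel_size, 3)
  expect_equal(spec$layers[[5]]$units, 100)

  lenet <- build_baseline("lenet", c(32, 32, 1), 10)
  types <- vapply(lenet$layers, function(l) l$type, "")
  expect_equal(types, c("conv", "relu", "pool", "conv", "relu", "pool",
                        "flatten", "dense", "relu", "dense", "relu", "dense"))
  expect_equal(vapply(lenet$layers[types == "conv"],
                      function(l) l$kernel_size, 0L), c(5L, 5L))
  dense_units <- vapply(lenet$layers[types == "dense"],
                        function(l) l$units, 0L)
  expect_equal(dense_units, c(120L, 84L, 10L))
  expect_equal(lenet$layers[[3]]$kind, "avg")
})

test_that("lenet adapts to tiny inputs via same-padding, with a note", {
  expect_message(spec <- build_baseline("lenet", c(3, 3, 3), 4),
                 "same-padding")
  expect_s3_class(spec, "model_spec")
  # the adapted model must still run forward
  params <- scsmap:::init_params(spec, 1)
  out <- scsmap:::model_forward(spec, params, array(rnorm(2 * 27),
                                                    c(2, 3, 3, 3)))
  expect_equal(dim(out$logits), c(2, 4))
})

test_that("unknown baseline names fail fast", {
  expect_error(build_baseline("xception", c(3, 3, 3), 4), "unknown")
})

test_that("training drives loss down sharply and fits a separable fixture", {
  ps <- separable_patches(seed = 4)
  sp <- stratified_split(ps, c(0.5, 0.2, 0.3), seed = 4)
  spec <- build_scs_classifier(c(3, 3, 3), 2)
  model <- train_model(spec, ps, sp,
                       training_config(epochs = 80, batch_size = 16,
                                       seed = 4))
  h <- model$history
  expect_equal(h$train_acc[nrow(h)], 1.0)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1] / 10)
  pred <- predict_labels(model, subset_patches(ps, sp$train))
  expect_equal(pred$labels, ps$labels[sp$train])
})

test_that("identical seeds give identical training histories", {
  ps <- separable_patches(n_per_class = 30, seed = 6)
  sp <- stratified_split(ps, c(0.5, 0.2, 0.3), seed = 6)
  spec <- build_scs_classifier(c(3, 3, 3), 2)
  cfg <- training_config(epochs = 10, batch_size = 16, seed = 9)
  m1 <- train_model(spec, ps, sp, cfg)
  m2 <- train_model(spec, ps, sp, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("degenerate training inputs are rejected", {
  ps <- separable_patches(n_per_class = 10, seed = 2)
  sp <- stratified_split(ps, c(0.5, 0.2, 0.3), seed = 2)
  spec <- build_scs_classifier(c(3, 3, 3), 2)
  single <- sp
  single$train <- which(ps$labels == 1)[1:5]
  expect_error(train_model(spec, ps, single, training_config(epochs = 1)),
               "single class")
  empty <- sp
  empty$train <- integer(0)
  expect_error(train_model(spec, ps, empty, training_config(epochs = 1)),
               "empty train")
})

test_that("predicted probabilities are proper and empty input yields empty output", {
  ps <- separable_patches(n_per_class = 15, seed = 3)
  sp <- stratified_split(ps, c(0.6, 0.2, 0.2), seed = 3)
  spec <- build_scs_classifier(c(3, 3, 3), 2)
  model <- train_model(spec, ps, sp, training_config(epochs = 3,
                                                     batch_size = 8,
                                                     seed = 3))
  pred <- predict_labels(model, ps)
  expect_equal(rowSums(pred$probs), rep(1, dim(ps$patches)[1]),
               tolerance = 1e-6)
  none <- predict_labels(model, ps$patches[integer(0), , , , drop = FALSE])
  expect_length(none$labels, 0)
})

test_that("frozen class-mean kernels reproduce nearest-cosine-prototype labels", {
  set.seed(21)
  D <- 3; C <- 4
  protos <- matrix(rnorm(C * 27), C, 27)
  X <- array(0, c(40, 3, 3, D))
  truth <- integer(40)
  for (i in 1:40) {
    cl <- sample.int(C, 1)
    truth[i] <- cl
    X[i, , , ] <- array(protos[cl, ] + rnorm(27, sd = 0.4), c(3, 3, D))
  }
  spec <- build_scs_classifier(c(3, 3, D), C,
                               scs_layer_config(n_units = C, q_init = 0,
                                                p_init = 1))
  params <- scsmap:::init_params(spec, 1)
  params[[1]]$W <- t(protos)          # one unit per class prototype
  params[[1]]$q <- rep(0, C)
  params[[1]]$p <- rep(1, C)
  params[[4]]$W <- diag(C)            # head passes scores through
  params[[4]]$b <- rep(0, C)
  model <- structure(list(spec = spec, params = params,
                          history = data.frame(), config = NULL,
                          class_names = letters[1:C]),
                     class = "trained_model")
  got <- predict_labels(model, X)$labels
  oracle <- apply(X, 1, function(p)
    which.max(vapply(seq_len(C), function(cl)
      cosine_oracle(protos[cl, ], as.vector(p)), numeric(1))))
  expect_equal(got, oracle)
})

test_that("full-scene prediction covers the grid and is constant on constant input", {
  ps <- separable_patches(n_per_class = 30, seed = 8)
  sp <- stratified_split(ps, c(0.5, 0.2, 0.3), seed = 8)
  spec <- build_scs_classifier(c(3, 3, 3), 2)
  model <- train_model(spec, ps, sp, training_config(epochs = 20,
                                                     batch_size = 16,
                                                     seed = 8))
  flat <- hyper_cube(array(0.7, c(10, 12, 3)))
  map <- predict_map(model, flat)
  expect_equal(dim(map$labels), c(10, 12))
  expect_length(unique(as.vector(map$labels)), 1)
  wrong <- hyper_cube(array(1, c(5, 5, 7)))
  expect_error(predict_map(model, wrong), "bands")
})
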