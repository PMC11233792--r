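# recompute every metric from raw label pairs, never via the matrix
brute_metrics <- function(truth, pred, C) {
  n <- length(truth)
  oa <- mean(truth == pred)
  ae <- sum(vapply(seq_len(C), function(cl)
    (sum(truth == cl) / n) * (sum(pred == cl) / n), numeric(1)))
  kappa <- (oa - ae) / (1 - ae)
  recalls <- vapply(seq_len(C), function(cl)
    if (sum(truth == cl) == 0) NA_real_
    else mean(pred[truth == cl] == cl), numeric(1))
  f1 <- vapply(seq_len(C), function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    pr <- if (tp + fp > 0) tp / (tp + fp) else 0
    rc <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }, numeric(1))
  list(oa = oa, ae = ae, kappa = kappa,
       aa = mean(recalls, na.rm = TRUE), f1 = f1)
}

test_that("confusion matrix counts match hand tallies", {
  cm <- confusion_matrix(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(unclass(unname(cm)), matrix(c(1L, 0L, 1L, 2L), 2, 2),
               ignore_attr = TRUE)
  diag_cm <- confusion_matrix(c(1, 2, 3), c(1, 2, 3))
  expect_equal(sum(diag_cm) - sum(diag(diag_cm)), 0L)
  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(1:3, 1:2), "length")
  expect_error(confusion_matrix(c(1, 5), c(1, 1), C = 2), "index 2")
})

test_that("the worked 2x2 case gives A_o 0.85, A_e 0.50, kappa 0.70", {
  cm <- confusion_matrix(rep(c(1, 1, 2, 2), c(40, 10, 5, 45)),
                         rep(c(1, 2, 1, 2), c(40, 10, 5, 45)))
  k <- cohens_kappa(cm)
  expect_equal(k$A_o, 0.85)
  expect_equal(k$A_e, 0.50)
  expect_equal(k$kappa, 0.70)
  expect_equal(overall_accuracy(cm), 0.85)
  expect_equal(average_accuracy(cm), 0.85)
  f1 <- f1_scores(cm)
  expect_equal(unname(f1$per_class[1]), 2 * (40 / 45) * 0.8 / (40 / 45 + 0.8))
})

test_that("kappa hits its boundary cases", {
  perfect <- matrix(c(30L, 0L, 0L, 20L), 2, 2)
  expect_equal(cohens_kappa(perfect)$kappa, 1)
  chance <- matrix(25L, 2, 2)
  expect_equal(cohens_kappa(chance)$kappa, 0)
  onecell <- matrix(c(10L, 0L, 0L, 0L), 2, 2)
  expect_warning(k <- cohens_kappa(onecell), "convention")
  expect_equal(k$kappa, 0)
})

test_that("average accuracy is macro recall; the (1, .5, 0) case gives 0.5", {
  cm <- matrix(c(2L, 1L, 3L, 0L, 1L, 0L, 0L, 0L, 0L), 3, 3)
  expect_equal(average_accuracy(cm), 0.5)
  expect_equal(overall_accuracy(matrix(c(0L, 3L, 2L, 0L), 2, 2)), 0)
})

test_that("a class never predicted nor correct gets F1 = 0 by convention", {
  cm <- matrix(c(5L, 2L, 0L, 0L, 0L, 0L, 0L, 0L, 4L), 3, 3)
  f1 <- f1_scores(cm)
  expect_equal(unname(f1$per_class[2]), 0)
})

test_that("all metrics agree with a from-scratch recount on random labels", {
  set.seed(30)
  for (rep in 1:40) {
    C <- sample(2:5, 1)
    n <- 25
    truth <- sample(seq_len(C), n, replace = TRUE)
    pred <- sample(seq_len(C), n, replace = TRUE)
    bf <- brute_metrics(truth, pred, C)
    cm <- confusion_matrix(truth, pred, C)
    kp <- suppressWarnings(cohens_kappa(cm))
    expect_equal(kp$A_e, bf$ae)
    expect_equal(kp$kappa, bf$kappa)
    expect_equal(overall_accuracy(cm), bf$oa)
    expect_equal(suppressWarnings(average_accuracy(cm)), bf$aa)
    expect_equal(unname(f1_scores(cm)$per_class), bf$f1)
    expect_gte(kp$kappa, -1); expect_lte(kp$kappa, 1)
    off_diag <- sum(cm) - sum(diag(cm))
    expect_equal(kp$kappa == 1, off_diag == 0L)
  }
})

test_that("permuting class order permutes F1 and leaves kappa/OA/AA unchanged", {
  set.seed(31)
  truth <- sample(1:4, 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.7, truth, sample(1:4, 200, replace = TRUE))
  perm <- c(3L, 1L, 4L, 2L)
  cm1 <- confusion_matrix(truth, pred, 4)
  cm2 <- confusion_matrix(perm[truth], perm[pred], 4)
  expect_equal(cohens_kappa(cm1)$kappa, cohens_kappa(cm2)$kappa)
  expect_equal(overall_accuracy(cm1), overall_accuracy(cm2))
  expect_equal(average_accuracy(cm1), average_accuracy(cm2))
  f1_1 <- unname(f1_scores(cm1)$per_class)
  f1_2 <- unname(f1_scores(cm2)$per_class)
  expect_equal(f1_2[perm], f1_1)
})

test_that("the literal printed variants exist but differ from the standard forms", {
  cm <- confusion_matrix(rep(c(1, 1, 2, 2), c(40, 10, 5, 45)),
                         rep(c(1, 2, 1, 2), c(40, 10, 5, 45)))
  lit <- cohens_kappa(cm, literal_binary = TRUE)
  expect_false(isTRUE(all.equal(lit$A_e, 0.50)))
  expect_error(cohens_kappa(matrix(1L, 3, 3), literal_binary = TRUE), "2 x 2")
  lit_aa <- average_accuracy(cm, literal = TRUE)
  expect_true(is.finite(lit_aa) && lit_aa >= 0 && lit_aa <= 1)
})

test_that("reports bundle all quantities and serialize to JSON and CSV", {
  rep <- metrics_report(true_labels = c(1, 1, 2, 2, 3, 3),
                        pred_labels = c(1, 2, 2, 2, 3, 3),
                        class_names = c("a", "b", "c"))
  expect_equal(rep$kappa, cohens_kappa(rep$confusion)$kappa)
  jpath <- tempfile(fileext = ".json")
  write_metrics(rep, jpath)
  parsed <- jsonlite::fromJSON(jpath)
  expect_equal(parsed$kappa, rep$kappa)
  expect_named(parsed$f1_per_class, c("a", "b", "c"))
  cpath <- tempfile(fileext = ".csv")
  write_metrics(rep, cpath)
  expect_equal(utils::read.csv(cpath)$overall_accuracy,
               rep$overall_accuracy)
})
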