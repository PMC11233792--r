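#' Confusion matrix from label vectors
#'
#' @param true_labels,pred_labels equal-length integer vectors with values in
#'   1..C.
#' @param C number of classes; defaults to the largest label seen.
#' @param class_names optional class names (length C).
#' @return A C x C integer matrix of class `confusion_matrix`; rows are true
#'   classes, columns predicted.
#' @export
confusion_matrix <- function(true_labels, pred_labels,
                             C = max(true_labels, pred_labels),
                             class_names = NULL) {
  if (length(true_labels) != length(pred_labels))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(true_labels), length(pred_labels)), call. = FALSE)
  if (length(true_labels) == 0L)
    stop("empty label vectors", call. = FALSE)
  C <- as.integer(C)
  bad <- which(true_labels < 1L | true_labels > C |
               pred_labels < 1L | pred_labels > C)
  if (length(bad))
    stop(sprintf("label outside 1..%d at index %d", C, bad[1L]),
         call. = FALSE)
  cm <- matrix(0L, C, C)
  tab <- table(factor(true_labels, levels = seq_len(C)),
               factor(pred_labels, levels = seq_len(C)))
  cm[] <- as.integer(tab)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(C))
  dimnames(cm) <- list(true = class_names, pred = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

as_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("`cm` must be a square non-negative matrix", call. = FALSE)
  if (sum(cm) == 0) stop("confusion matrix has zero total", call. = FALSE)
  cm
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (A_o - A_e) / (1 - A_e), where the
#' observed agreement A_o is the diagonal fraction and the expected agreement
#' A_e is the sum over classes of the products of row and column marginal
#' probabilities. By convention kappa = 0 (with a warning) when A_e = 1,
#' which happens only when all mass sits in a single cell of a single
#' row/column pair.
#'
#' `literal_binary = TRUE` instead evaluates, for 2 x 2 matrices only, the
#' nonstandard printed variant of the expected-agreement formula
#' (A_e = (FN+TN)/n * (FP+TN)/n + (TP+FN)/n) so the difference from the
#' standard definition can be inspected; it is not used anywhere in the
#' pipeline.
#'
#' @param cm a [confusion_matrix()] (or any square count matrix).
#' @param literal_binary evaluate the nonstandard binary variant (see above).
#' @return List with `kappa`, `A_o`, `A_e`.
#' @export
cohens_kappa <- function(cm, literal_binary = FALSE) {
  cm <- as_cm(cm)
  n <- sum(cm)
  A_o <- sum(diag(cm)) / n
  if (literal_binary) {
    if (nrow(cm) != 2L)
      stop("`literal_binary` mode is defined for 2 x 2 matrices only",
           call. = FALSE)
    TP <- cm[1L, 1L]; FN <- cm[1L, 2L]; FP <- cm[2L, 1L]; TN <- cm[2L, 2L]
    A_e <- ((FN + TN) / n) * ((FP + TN) / n) + (TP + FN) / n
  } else {
    A_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  }
  if (A_e >= 1) {
    warning("expected agreement is 1; returning kappa = 0 by convention",
            call. = FALSE)
    return(list(kappa = 0, A_o = A_o, A_e = A_e))
  }
  list(kappa = (A_o - A_e) / (1 - A_e), A_o = A_o, A_e = A_e)
}

#' Overall accuracy
#'
#' Fraction of correctly classified samples: trace / total.
#'
#' @param cm a [confusion_matrix()].
#' @return A number in [0, 1].
#' @export
overall_accuracy <- function(cm) {
  cm <- as_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' Average accuracy
#'
#' Unweighted mean over classes of per-class recall TP_c / (TP_c + FN_c) —
#' the standard definition of average accuracy in hyperspectral
#' classification. Classes with no true samples are excluded with a warning.
#' `literal = TRUE` evaluates the nonstandard printed variant
#' (TP+TN)/(TP+TN+FN) with one-vs-rest tallies averaged over classes, for
#' inspection only.
#'
#' @param cm a [confusion_matrix()].
#' @param literal evaluate the nonstandard variant (see above).
#' @return A number in [0, 1].
#' @export
average_accuracy <- function(cm, literal = FALSE) {
  cm <- as_cm(cm)
  rs <- rowSums(cm)
  if (all(rs == 0)) stop("no class has any true sample", call. = FALSE)
  if (any(rs == 0))
    warning(sprintf("excluding %d class(es) with no true samples",
                    sum(rs == 0)), call. = FALSE)
  keep <- rs > 0
  if (literal) {
    n <- sum(cm)
    vals <- vapply(which(keep), function(c) {
      TP <- cm[c, c]; FN <- rs[c] - TP
      TN <- n - rs[c] - (colSums(cm)[c] - TP)
      (TP + TN) / (TP + TN + FN)
    }, numeric(1L))
    return(mean(vals))
  }
  mean(diag(cm)[keep] / rs[keep])
}

#' Per-class and macro F1 scores
#'
#' One-vs-rest precision TP/(TP+FP) and recall TP/(TP+FN) per class;
#' F1 = 2PR/(P+R), defined as 0 when P + R = 0. The macro score is the
#' unweighted mean; the weighted score (weights = class support) is also
#' returned since reported aggregate F1 values are often support-weighted.
#'
#' @param cm a [confusion_matrix()].
#' @return List with `per_class` (named numeric), `macro`, `weighted`,
#'   `precision`, `recall`.
#' @export
f1_scores <- function(cm) {
  cm <- as_cm(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  nm <- rownames(cm) %||% paste0("class", seq_len(nrow(cm)))
  names(f1) <- names(precision) <- names(recall) <- nm
  support <- rowSums(cm)
  weighted <- if (sum(support) > 0) sum(f1 * support) / sum(support) else 0
  list(per_class = f1, macro = mean(f1), weighted = weighted,
       precision = precision, recall = recall)
}

#' Full metrics report
#'
#' Bundles Cohen's kappa (with observed/expected agreement), overall
#' accuracy, average accuracy, and per-class/macro/weighted F1 from one
#' confusion matrix.
#'
#' @param cm a [confusion_matrix()], or `NULL` to build one from labels.
#' @param true_labels,pred_labels used when `cm` is `NULL`.
#' @param class_names optional class names.
#' @return An object of class `metrics_report`.
#' @export
metrics_report <- function(cm = NULL, true_labels = NULL, pred_labels = NULL,
                           class_names = NULL) {
  if (is.null(cm))
    cm <- confusion_matrix(true_labels, pred_labels,
                           C = if (is.null(class_names))
                                 max(true_labels, pred_labels)
                               else length(class_names),
                           class_names = class_names)
  kp <- cohens_kappa(cm)
  f1 <- f1_scores(cm)
  structure(list(kappa = kp$kappa, A_o = kp$A_o, A_e = kp$A_e,
                 overall_accuracy = overall_accuracy(cm),
                 average_accuracy = average_accuracy(cm),
                 f1_per_class = f1$per_class, f1_macro = f1$macro,
                 f1_weighted = f1$weighted,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> kappa %.4f | OA %.4f | AA %.4f | F1 macro %.4f (weighted %.4f)\n",
    x$kappa, x$overall_accuracy, x$average_accuracy, x$f1_macro,
    x$f1_weighted))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report a [metrics_report()].
#' @param path output path; `.json` or `.csv` decides the format.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(kappa = report$kappa, overall_accuracy = report$overall_accuracy,
           average_accuracy = report$average_accuracy,
           f1_macro = report$f1_macro, f1_weighted = report$f1_weighted,
           f1_per_class = as.list(report$f1_per_class),
           A_o = report$A_o, A_e = report$A_e),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(
      kappa = report$kappa, overall_accuracy = report$overall_accuracy,
      average_accuracy = report$average_accuracy,
      f1_macro = report$f1_macro, f1_weighted = report$f1_weighted),
      path, row.names = FALSE)
  }
  invisible(path)
}
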