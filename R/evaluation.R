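# Evaluation suite: confusion matrix, one-vs-rest per-class metrics
# (precision, sensitivity, specificity, F1), macro / support-weighted
# aggregation, multiclass Jaccard, one-vs-rest ROC-AUC. All rates are
# reported in percent, matching the conventions of the benchmark tables.

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param labels Ordered label vocabulary (default: sorted union).
#' @return A `confusion_matrix`: K x K integer matrix with dimnames.
#' @export
confusion_matrix <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    abort("y_true and y_pred lengths differ.", class = "ecsanet_invalid_input")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(unknown) > 0)
    abort(sprintf("Unknown label(s): %s.", paste(unknown, collapse = ", ")),
          class = "ecsanet_invalid_input")
  cm <- table(factor(y_true, levels = labels), factor(y_pred, levels = labels))
  structure(unclass(cm), dimnames = list(true = labels, pred = labels),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted)\n")
  print(matrix(x, nrow = nrow(x), dimnames = dimnames(x)))
  invisible(x)
}

ovr_counts <- function(cm, cls) {
  i <- match(cls, rownames(cm))
  tp <- cm[i, i]
  fp <- sum(cm[-i, i])
  fn <- sum(cm[i, -i])
  tn <- sum(cm) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_rate <- function(num, den, what) {
  if (den == 0) {
    warn(sprintf("Zero denominator for %s; reporting 0.", what))
    return(0)
  }
  unname(num / den)
}

#' One-vs-rest metrics per class
#'
#' For each class: precision `TP/(TP+FP)`, sensitivity (recall)
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)`, and F1 as the harmonic mean of
#' precision and sensitivity, all in percent, plus the class support. A zero
#' denominator yields 0 with a warning.
#'
#' @param cm A [confusion_matrix()].
#' @param class Optional single class; default all classes.
#' @return Tibble with columns `label`, `precision`, `sensitivity`,
#'   `specificity`, `f1`, `support`.
#' @export
class_metrics <- function(cm, class = NULL) {
  labels <- if (is.null(class)) rownames(cm) else class
  purrr::map_dfr(labels, function(cls) {
    k <- ovr_counts(cm, cls)
    prec <- safe_rate(k["tp"], k["tp"] + k["fp"], paste0("precision(", cls, ")"))
    sens <- safe_rate(k["tp"], k["tp"] + k["fn"], paste0("sensitivity(", cls, ")"))
    spec <- safe_rate(k["tn"], k["fp"] + k["tn"], paste0("specificity(", cls, ")"))
    f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    tibble::tibble(label = cls, precision = 100 * prec, sensitivity = 100 * sens,
                   specificity = 100 * spec, f1 = 100 * f1,
                   support = unname(k["tp"] + k["fn"]))
  })
}

#' F1 from a precision / sensitivity pair (percent scale)
#'
#' Harmonic mean `2 p s / (p + s)`; the algebra is scale-invariant so percent
#' inputs give percent output.
#'
#' @param precision,sensitivity Rates in percent.
#' @return F1 in percent.
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity == 0, 0,
         2 * precision * sensitivity / (precision + sensitivity))
}

#' Macro and support-weighted aggregate rows
#'
#' Macro: unweighted mean over classes. Weighted: support-weighted mean.
#' For single-label multiclass data the weighted sensitivity equals the
#' overall accuracy.
#'
#' @param per_class A [class_metrics()] tibble.
#' @return Tibble with rows `macro` and `weighted`.
#' @export
aggregate_metrics <- function(per_class) {
  cols <- c("precision", "sensitivity", "specificity", "f1")
  w <- per_class$support / sum(per_class$support)
  dplyr::bind_rows(
    tibble::tibble(label = "macro",
                   !!!stats::setNames(lapply(cols, function(c) mean(per_class[[c]])), cols),
                   support = sum(per_class$support)),
    tibble::tibble(label = "weighted",
                   !!!stats::setNames(lapply(cols, function(c) sum(w * per_class[[c]])), cols),
                   support = sum(per_class$support)))
}

#' Multiclass Jaccard similarity
#'
#' Macro average over classes of the one-vs-rest intersection-over-union
#' `TP / (TP + FP + FN)`, in percent.
#'
#' @inheritParams confusion_matrix
#' @return Percentage in `[0, 100]`.
#' @export
jaccard_index <- function(y_true, y_pred, labels = NULL) {
  cm <- confusion_matrix(y_true, y_pred, labels)
  j <- vapply(rownames(cm), function(cls) {
    k <- ovr_counts(cm, cls)
    den <- k["tp"] + k["fp"] + k["fn"]
    if (den == 0) 0 else unname(k["tp"] / den)
  }, numeric(1))
  100 * mean(j)
}

#' One-vs-rest ROC-AUC, macro-averaged
#'
#' Per class, the area under the sensitivity versus (1 - specificity) curve
#' over all score thresholds, computed in the rank (Mann-Whitney) form
#' `AUC = P(score_pos > score_neg) + 0.5 P(tie)`; classes absent from
#' `y_true` are skipped with a warning. The macro average is returned in
#' percent.
#'
#' @param scores `N x K` matrix of class scores/probabilities with class
#'   column names.
#' @param y_true Length-N true labels.
#' @return Percentage in `[0, 100]`.
#' @export
roc_auc <- function(scores, y_true) {
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes))
    abort("`scores` needs class column names.", class = "ecsanet_invalid_input")
  y_true <- as.character(y_true)
  aucs <- c()
  for (cls in classes) {
    pos <- y_true == cls
    if (!any(pos)) {
      warn(sprintf("Class '%s' absent from y_true; skipped in AUC.", cls))
      next
    }
    if (all(pos)) next
    s <- scores[, cls]
    r <- rank(s)
    n_pos <- sum(pos); n_neg <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg))
  }
  100 * mean(aucs)
}

#' Full metrics report for a model on a held-out stream
#'
#' Emits the per-class table, macro/weighted aggregate rows, overall
#' accuracy, multiclass Jaccard, and macro one-vs-rest AUC, together with
#' the confusion matrix -- the complete evaluation block used for benchmark
#' reporting. The single-label identity `weighted sensitivity == accuracy`
#' is asserted on every report.
#'
#' @param model An `ecsanet_model`.
#' @param stream A [tensor_stream()] of held-out items.
#' @param out_dir Optional directory: writes `per_class.csv`,
#'   `report.json` (full precision) and `confusion.csv`.
#' @return A `metrics_report`.
#' @export
evaluate_model <- function(model, stream, out_dir = NULL) {
  if (stream$n == 0) abort("Empty stream.", class = "ecsanet_invalid_input")
  ev <- eval_stream_loss(model, stream)
  metrics_report(stream$y, ev$pred, scores = ev$probs,
                 labels = model$class_labels, out_dir = out_dir)
}

#' @param y_true,y_pred Label vectors.
#' @param scores Optional `N x K` score matrix for AUC.
#' @param labels Label vocabulary.
#' @rdname evaluate_model
#' @export
metrics_report <- function(y_true, y_pred, scores = NULL, labels = NULL,
                           out_dir = NULL) {
  cm <- confusion_matrix(y_true, y_pred, labels)
  per_class <- class_metrics(cm)
  agg <- aggregate_metrics(per_class)
  accuracy <- 100 * sum(diag(cm)) / sum(cm)
  stopifnot(abs(agg$sensitivity[agg$label == "weighted"] - accuracy) < 1e-9)
  auc <- if (!is.null(scores)) roc_auc(scores, y_true) else NA_real_
  rep <- structure(list(
    per_class = per_class, macro = agg[agg$label == "macro", ],
    weighted = agg[agg$label == "weighted", ], accuracy = accuracy,
    jaccard = jaccard_index(y_true, y_pred, rownames(cm)),
    auc = auc, auc_scheme = "one-vs-rest, macro-averaged",
    confusion = cm, n = sum(cm)), class = "metrics_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(dplyr::bind_rows(per_class, agg),
                     file.path(out_dir, "per_class.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame.matrix(matrix(cm, nrow(cm),
                                                 dimnames = dimnames(cm))),
                     file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(list(accuracy = rep$accuracy, jaccard = rep$jaccard,
                              auc = rep$auc, auc_scheme = rep$auc_scheme,
                              per_class = per_class, aggregates = agg),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report (n = %d)\n", x$n))
  fmt <- dplyr::mutate(dplyr::bind_rows(x$per_class, x$macro, x$weighted),
                       dplyr::across(c("precision", "sensitivity", "f1"), round),
                       specificity = round(.data$specificity, 2))
  print(fmt, n = Inf)
  cat(sprintf("accuracy %.2f%%  jaccard %.2f%%  AUC %s%%\n", x$accuracy,
              x$jaccard, ifelse(is.na(x$auc), "NA", sprintf("%.2f", x$auc))))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) {
  dplyr::bind_rows(x$per_class, x$macro, x$weighted)
}

#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy,
                 precision_macro = x$macro$precision,
                 precision_weighted = x$weighted$precision,
                 f1_macro = x$macro$f1, jaccard = x$jaccard, auc = x$auc,
                 n = x$n)
}

#' Confusion-matrix heat map
#'
#' @param object A `metrics_report` (or `confusion_matrix`).
#' @param ... Unused.
#' @return A ggplot heat map, rows true classes, columns predicted.
#' @export
autoplot.metrics_report <- function(object, ...) plot_confusion(object$confusion)

#' @rdname autoplot.metrics_report
#' @param cm A `confusion_matrix`.
#' @export
plot_confusion <- function(cm) {
  df <- tibble::as_tibble(as.data.frame(as.table(
    matrix(cm, nrow(cm), dimnames = dimnames(cm)))))
  names(df) <- c("true", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), color = "grey20") +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#4a1486") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
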