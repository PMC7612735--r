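# Per-class precision/recall/F1, learning curves, hierarchy consistency.

#' Confusion counts between true and predicted labels
#'
#' Rows are the true classes (sorted); columns are all labels seen in either
#' vector, with `"Unassigned"` allowed as a predicted column but never a true
#' row. Entry (i, j) counts cells with true class i predicted j.
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @return An integer matrix with dimnames.
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_validation("true and predicted label vectors differ in length")
  }
  if (any(true_labels == "Unassigned")) {
    stop_validation("'Unassigned' cannot appear as a true label")
  }
  rows <- sort(unique(true_labels))
  cols <- sort(unique(c(true_labels, predicted_labels)))
  if ("Unassigned" %in% cols) {
    cols <- c(setdiff(cols, "Unassigned"), "Unassigned")
  }
  tab <- table(factor(true_labels, levels = rows),
               factor(predicted_labels, levels = cols))
  m <- matrix(as.integer(tab), nrow = length(rows),
              dimnames = list(true = rows, predicted = cols))
  m
}

#' Per-class precision, recall and F1 with a median-F1 summary
#'
#' For each true class c: precision = TP / (TP + FP) over cells predicted c
#' (0 when nothing is predicted c), recall = TP / (TP + FN), and
#' F1 = 2PR / (P + R) with F1 = 0 when P + R = 0. `"Unassigned"` predictions
#' count as false negatives for the true class and enter no class's precision
#' denominator. The summary statistic is the median of per-class F1 over
#' classes with non-zero support; the macro mean is reported alongside.
#'
#' @param confusion A matrix from [confusion_counts()].
#' @return A `MetricsReport`: list with `per_class` (data frame: class,
#'   precision, recall, f1, support), `median_f1` and `macro_f1`.
#' @export
precision_recall_f1 <- function(confusion) {
  if (sum(confusion) == 0) stop_validation("empty confusion table")
  classes <- rownames(confusion)
  pred_cols <- colnames(confusion)
  support <- rowSums(confusion)
  prec <- rec <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    c <- classes[i]
    tp <- if (c %in% pred_cols) confusion[c, c] else 0
    pred_total <- if (c %in% pred_cols) sum(confusion[, c]) else 0
    prec[i] <- if (pred_total > 0) tp / pred_total else 0
    rec[i] <- if (support[i] > 0) tp / support[i] else 0
    f1[i] <- if (prec[i] + rec[i] > 0) {
      2 * prec[i] * rec[i] / (prec[i] + rec[i])
    } else 0
  }
  per_class <- data.frame(class = classes, precision = prec, recall = rec,
                          f1 = f1, support = as.integer(support),
                          stringsAsFactors = FALSE)
  with_support <- support > 0
  structure(
    list(per_class = per_class,
         median_f1 = stats::median(f1[with_support]),
         macro_f1 = mean(f1[with_support])),
    class = "MetricsReport"
  )
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("<MetricsReport> median F1 = %.4f, macro F1 = %.4f\n",
              x$median_f1, x$macro_f1))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as TSV
#' @param x A `MetricsReport`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(x, path) {
  utils::write.table(x$per_class, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Seeded stratified split: returns validation indices, at least one cell per
# class whenever the class has more than one cell.
stratified_validation_split <- function(labels, fraction, seed) {
  labels <- as.character(labels)
  withr::with_seed(as.integer(seed), {
    val <- integer()
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      n_val <- max(1L, floor(fraction * length(idx)))
      if (length(idx) < 2L) next   # singleton classes stay in training
      val <- c(val, sample(idx, n_val))
    }
    sort(val)
  })
}

#' Median-F1 learning curve over training iterations
#'
#' Holds out a seeded stratified validation split, then trains both rounds
#' while scoring the current model on the split at every epoch boundary:
#' the curve has one point per epoch per round. Classes absent from the
#' validation split are excluded from the median (with a warning).
#'
#' @inheritParams fit_round
#' @return A data frame with columns `round`, `epoch`, `iteration` and
#'   `median_f1`, with the final model attached as attribute `"model"`.
#' @export
f1_learning_curve <- function(X, labels, config = training_config()) {
  labels <- as.character(labels)
  val_idx <- stratified_validation_split(labels, config$validation_fraction,
                                         config$seed)
  if (length(val_idx) == 0L) {
    stop_validation("validation split is empty")
  }
  tr_idx <- setdiff(seq_along(labels), val_idx)
  Xtr <- normalized_matrix(X$values[tr_idx, , drop = FALSE],
                           X$cell_ids[tr_idx], X$gene_ids,
                           target_sum = X$target_sum,
                           transform = X$transform)
  Xval <- normalized_matrix(X$values[val_idx, , drop = FALSE],
                            X$cell_ids[val_idx], X$gene_ids,
                            target_sum = X$target_sum,
                            transform = X$transform)
  ytr <- labels[tr_idx]
  yval <- labels[val_idx]
  missing_val <- setdiff(unique(ytr), unique(yval))
  if (length(missing_val)) {
    warning(sprintf("classes absent from validation split: %s",
                    paste(missing_val, collapse = ", ")), call. = FALSE)
  }
  rows <- list()
  score <- function(model, round, epoch, iteration) {
    pred <- predict_probabilities(model, Xval)
    rep <- precision_recall_f1(confusion_counts(yval, pred$predicted_label))
    rows[[length(rows) + 1L]] <<- data.frame(
      round = round, epoch = epoch, iteration = iteration,
      median_f1 = rep$median_f1)
  }
  n_b1 <- length(make_minibatches(length(tr_idx), config$batch_size,
                                  config$seed))
  r1 <- fit_round(Xtr, ytr, config,
                  eval_fun = function(m, e) score(m, 1L, e, e * n_b1))
  feats <- select_top_features(r1$model, config$n_top_genes)
  r2 <- fit_round(Xtr, ytr, config, feature_subset = feats,
                  eval_fun = function(m, e) score(m, 2L, e, e * n_b1))
  curve <- do.call(rbind, rows)
  attr(curve, "model") <- r2$model
  curve
}

#' Fraction of cells with hierarchy-consistent fine/coarse predictions
#'
#' @param pred_low Predicted fine (low-hierarchy) labels.
#' @param pred_high Predicted coarse (high-hierarchy) labels, same length.
#' @param h A [label_hierarchy()] covering every `pred_low` label.
#' @return The fraction of cells whose mapped fine label equals the coarse
#'   prediction; 1 (vacuously, with a log note) for empty input.
#' @export
hierarchy_consistency <- function(pred_low, pred_high, h) {
  stopifnot(inherits(h, "LabelHierarchy"))
  pred_low <- as.character(pred_low)
  pred_high <- as.character(pred_high)
  if (length(pred_low) != length(pred_high)) {
    stop_validation("prediction vectors differ in length")
  }
  if (length(pred_low) == 0L) {
    st_log("hierarchy_consistency on empty input: vacuously 1")
    return(1)
  }
  missing <- setdiff(unique(pred_low), names(h$low_to_high))
  if (length(missing)) {
    stop_validation(sprintf("low labels missing from hierarchy: %s",
                            paste(missing, collapse = ", ")),
                    category = "hierarchy")
  }
  mean(unname(h$low_to_high[pred_low]) == pred_high)
}
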