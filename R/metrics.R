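#' Tabulate a confusion matrix
#'
#' Entry `(p, r)` counts instances predicted as class `p` whose real class is
#' `r`: rows are predictions, columns are real classes.
#'
#' @param true_labels,predicted_labels Equal-length vectors of class codes
#'   (1-based integers) or factors sharing the class order.
#' @param C Class count; defaults to the factor level count or max code.
#' @param class_names Optional dimnames.
#' @return A `C x C` integer matrix of class `ctg_confusion`.
#' @export
confusion_counts <- function(true_labels, predicted_labels, C = NULL,
                             class_names = NULL) {
  if (length(true_labels) != length(predicted_labels)) {
    stop_input("true and predicted label vectors differ in length")
  }
  if (is.factor(true_labels) && is.null(class_names)) class_names <- levels(true_labels)
  ti <- if (is.factor(true_labels)) as.integer(true_labels) else as.integer(true_labels)
  pi <- if (is.factor(predicted_labels)) as.integer(predicted_labels) else as.integer(predicted_labels)
  if (is.null(C)) C <- max(ti, pi, length(class_names))
  if (any(ti < 1 | ti > C | pi < 1 | pi > C)) stop_input("label code outside 1..C")
  m <- matrix(0L, C, C)
  for (i in seq_along(ti)) m[pi[i], ti[i]] <- m[pi[i], ti[i]] + 1L
  if (!is.null(class_names)) dimnames(m) <- list(predicted = class_names,
                                                 real = class_names)
  structure(m, class = c("ctg_confusion", class(m)))
}

#' Column-normalize a confusion matrix
#'
#' Divides each column (real class) by its total, giving class-conditional
#' rates: the diagonal is per-class recall. Empty real classes yield a zero
#' column, flagged in the `"empty_classes"` attribute rather than failing.
#'
#' @param counts A confusion matrix (predictions x real classes).
#' @return Numeric matrix whose non-empty columns each sum to 1.
#' @export
normalize_confusion <- function(counts) {
  m <- unclass(counts)
  tot <- colSums(m)
  empty <- tot == 0
  out <- sweep(m, 2, ifelse(empty, 1, tot), "/")
  out[, empty] <- 0
  if (any(empty)) attr(out, "empty_classes") <- which(empty)
  out
}

#' Compute classification metrics from a confusion matrix
#'
#' Multi-class accuracy is the fraction correct (trace / total). Per-class
#' precision, recall and F1 come from the one-vs-rest reduction; F1 is the
#' harmonic mean of precision and recall. Macro values are unweighted means
#' over classes; prevalence-weighted means are also reported. Metrics whose
#' denominator is zero are set to 0 and flagged.
#'
#' @param counts A confusion matrix from [confusion_counts()] (predictions in
#'   rows, real classes in columns).
#' @param average Which average populates the `precision`/`recall`/`f1`
#'   summary fields: `"macro"` (default) or `"weighted"` (by real-class
#'   prevalence).
#' @return An object of class `metrics_report`: accuracy, per-class and
#'   macro/weighted precision, recall and F1, the column-normalized confusion
#'   matrix, the raw counts and zero-denominator flags.
#' @export
compute_metrics <- function(counts, average = c("macro", "weighted")) {
  average <- match.arg(average)
  m <- unclass(counts)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_input("counts must be square")
  total <- sum(m)
  if (total < 1) stop_input("empty confusion matrix")
  tp <- diag(m)
  fp <- rowSums(m) - tp   # predicted c, real other
  fn <- colSums(m) - tp   # real c, predicted other
  safe_div <- function(num, den) ifelse(den == 0, 0, num / ifelse(den == 0, 1, den))
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  flags <- list(precision = which(tp + fp == 0), recall = which(tp + fn == 0),
                f1 = which(precision + recall == 0))
  w <- colSums(m) / total
  pick <- function(x) if (average == "macro") mean(x) else sum(w * x)
  nm <- colnames(m)
  if (!is.null(nm)) names(precision) <- names(recall) <- names(f1) <- nm
  structure(list(
    accuracy = sum(tp) / total,
    per_class = list(precision = precision, recall = recall, f1 = f1),
    precision = pick(precision), recall = pick(recall), f1 = pick(f1),
    macro = list(precision = mean(precision), recall = mean(recall), f1 = mean(f1)),
    weighted = list(precision = sum(w * precision), recall = sum(w * recall),
                    f1 = sum(w * f1)),
    confusion_normalized = normalize_confusion(m),
    counts = m, n = total, average = average,
    zero_denominator = flags
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  accuracy=%.4f  %s: P=%.4f R=%.4f F1=%.4f\n",
              x$n, x$accuracy, x$average, x$precision, x$recall, x$f1))
  invisible(x)
}

# Unweighted field-wise mean of per-fold metrics reports.
average_reports <- function(reports) {
  avg <- reports[[1L]]
  num_fields <- c("accuracy", "precision", "recall", "f1")
  for (f in num_fields) avg[[f]] <- mean(vapply(reports, `[[`, 0, f))
  for (blk in c("macro", "weighted")) {
    for (f in names(avg[[blk]])) {
      avg[[blk]][[f]] <- mean(vapply(reports, function(r) r[[blk]][[f]], 0))
    }
  }
  for (f in names(avg$per_class)) {
    avg$per_class[[f]] <- rowMeans(vapply(reports, function(r) r$per_class[[f]],
                                          numeric(length(avg$per_class[[f]]))))
  }
  avg$confusion_normalized <- Reduce(`+`, lapply(reports, `[[`, "confusion_normalized")) /
    length(reports)
  avg$counts <- Reduce(`+`, lapply(reports, `[[`, "counts"))
  avg$n <- sum(vapply(reports, `[[`, 0, "n"))
  avg
}

#' Cross-validate a learner or stacked ensemble
#'
#' Runs stratified k-fold cross-validation. Inside each fold, normalization
#' parameters and all models are fitted on the training portion only; the
#' held-out fold is transformed with the training fold's parameters before
#' prediction. The final report averages the per-fold metric values
#' (fold-level averaging, not prediction pooling); per-fold reports are
#' retained.
#'
#' @param dataset A [ctg_dataset()].
#' @param config A [learner_spec()] or a [stacking_config()].
#' @param k Fold count (default 10).
#' @param seed Integer seed for the fold assignment and per-fold model seeds.
#' @param split Optional precomputed k-fold `ctg_split` (used to share folds
#'   across runs); overrides `k` and `seed` for the assignment.
#' @param average Passed to [compute_metrics()].
#' @return List with `average` (a `metrics_report`), `folds` (per-fold
#'   reports) and `split`.
#' @export
cross_validate <- function(dataset, config, k = 10, seed = 1, split = NULL,
                           average = "macro") {
  stopifnot(inherits(dataset, "ctg_dataset"))
  cls_n <- table(dataset$labels)
  if (is.null(split)) {
    if (any(cls_n < k)) {
      stop_config("class '", names(cls_n)[which.min(cls_n)], "' has fewer than k = ",
                  k, " instances")
    }
    split <- make_split(dataset$labels, "kfold", k = k, seed = seed)
  }
  k <- split$k
  fold_seeds <- derive_seeds(seed, k)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- split$assignments != f
    te <- !tr
    if (inherits(config, "ctg_stacking_config")) {
      cfg <- config
      cfg$seed <- fold_seeds[f]
      model <- fit_stacked(cfg, dataset_subset(dataset, tr))
      pred <- predict(model, dataset$features[te, , drop = FALSE], type = "class")
    } else if (inherits(config, "ctg_learner_spec")) {
      cfg <- config
      cfg$seed <- fold_seeds[f]
      if (config$family == "oracle") {
        # the oracle testing family applies a rule in raw feature units
        xtr <- dataset$features[tr, , drop = FALSE]
        xte <- dataset$features[te, , drop = FALSE]
      } else {
        norm <- fit_normalization(dataset$features[tr, , drop = FALSE])
        xtr <- suppressWarnings(apply_normalization(dataset$features[tr, , drop = FALSE], norm))
        xte <- suppressWarnings(apply_normalization(dataset$features[te, , drop = FALSE], norm))
      }
      model <- fit_learner(cfg, xtr, dataset$labels[tr], dataset$class_names)
      pred <- predict(model, xte, type = "class")
    } else {
      stop_config("config must be a learner_spec or stacking_config")
    }
    cm <- confusion_counts(dataset$labels[te], pred,
                           C = length(dataset$class_names),
                           class_names = dataset$class_names)
    reports[[f]] <- compute_metrics(cm, average = average)
  }
  list(average = average_reports(reports), folds = reports, split = split)
}

#' Evaluate on a stratified hold-out partition
#'
#' Fits on a random training fraction (default 70%) and reports metrics on
#' the remainder, including the class-conditional (column-normalized)
#' confusion matrix.
#'
#' @inheritParams cross_validate
#' @param fraction Training fraction (default 0.7).
#' @return List with `report` (a `metrics_report`), the fitted `model` and
#'   the `split`.
#' @export
holdout_evaluate <- function(dataset, config, fraction = 0.7, seed = 1,
                             average = "macro") {
  stopifnot(inherits(dataset, "ctg_dataset"))
  split <- make_split(dataset$labels, "holdout", fraction = fraction, seed = seed)
  tr <- split$assignments == "train"
  te <- !tr
  if (inherits(config, "ctg_stacking_config")) {
    model <- fit_stacked(config, dataset_subset(dataset, tr))
    pred <- predict(model, dataset$features[te, , drop = FALSE], type = "class")
  } else {
    if (config$family == "oracle") {
      xtr <- dataset$features[tr, , drop = FALSE]
      xte <- dataset$features[te, , drop = FALSE]
    } else {
      norm <- fit_normalization(dataset$features[tr, , drop = FALSE])
      xtr <- suppressWarnings(apply_normalization(dataset$features[tr, , drop = FALSE], norm))
      xte <- suppressWarnings(apply_normalization(dataset$features[te, , drop = FALSE], norm))
    }
    model <- fit_learner(config, xtr, dataset$labels[tr], dataset$class_names)
    pred <- predict(model, xte, type = "class")
  }
  cm <- confusion_counts(dataset$labels[te], pred,
                         C = length(dataset$class_names),
                         class_names = dataset$class_names)
  list(report = compute_metrics(cm, average = average), model = model, split = split)
}
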