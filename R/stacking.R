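#' Configure a stacked ensemble
#'
#' Two-tier stacked generalization: base learners produce class
#' probabilities; a meta learner is trained on one of four meta-feature
#' strategies. The default configuration mirrors the classical CTG setup —
#' kernel SVM, gradient-boosted trees and a random forest as base learners,
#' a backpropagation network as meta learner, and the mixed strategy
#' (base-learner class probabilities concatenated with the original
#' features) as meta input.
#'
#' @param base_specs List of [learner_spec()] objects (>= 1).
#' @param meta_spec [learner_spec()] for the meta learner.
#' @param strategy Meta-feature strategy: `"labels"` (one-hot predicted
#'   labels), `"probabilities"`, `"labels_plus_features"` or
#'   `"probabilities_plus_features"` (the mixed strategy).
#' @param oof_folds Internal fold count (>= 2) for out-of-fold meta-feature
#'   generation.
#' @param seed Integer seed fanned out to every stochastic component.
#' @return An object of class `ctg_stacking_config`.
#' @export
stacking_config <- function(base_specs = list(learner_spec("kernel_margin"),
                                              learner_spec("boosted_trees"),
                                              learner_spec("bagged_trees")),
                            meta_spec = learner_spec("backprop_net"),
                            strategy = c("probabilities_plus_features", "labels",
                                         "probabilities", "labels_plus_features"),
                            oof_folds = 5, seed = 1) {
  strategy <- match.arg(strategy)
  if (inherits(base_specs, "ctg_learner_spec")) base_specs <- list(base_specs)
  if (!length(base_specs) || !all(vapply(base_specs, inherits, TRUE, "ctg_learner_spec"))) {
    stop_config("base_specs must be a non-empty list of learner_spec objects")
  }
  stopifnot(inherits(meta_spec, "ctg_learner_spec"))
  if (!is_count(oof_folds) || oof_folds < 2) stop_config("oof_folds must be >= 2")
  structure(list(base_specs = base_specs, meta_spec = meta_spec,
                 strategy = strategy, oof_folds = as.integer(oof_folds),
                 seed = as.integer(seed)),
            class = "ctg_stacking_config")
}

.strategies <- c("labels", "probabilities", "labels_plus_features",
                 "probabilities_plus_features")

#' Assemble meta-learner input features
#'
#' Builds the meta-learner design matrix for a strategy from per-base-learner
#' probability matrices and (for the `*_plus_features` strategies) the
#' original feature matrix. Label strategies one-hot encode each base
#' learner's argmax prediction, so every strategy contributes `B * C` learner
#' columns (learner-major, then class), with the original features appended
#' last in dataset order.
#'
#' @param strategy One of the four strategy codes.
#' @param base_outputs List of n x C probability matrices, one per base
#'   learner, identical row counts.
#' @param original_features n x M matrix (required for the `*_plus_features`
#'   strategies).
#' @return n x W matrix with `W = B*C` or `B*C + M`.
#' @export
build_meta_features <- function(strategy, base_outputs, original_features = NULL) {
  strategy <- match.arg(strategy, .strategies)
  if (!length(base_outputs)) stop_input("need at least one base output")
  n <- nrow(base_outputs[[1L]])
  if (!all(vapply(base_outputs, nrow, 0L) == n)) {
    stop_input("base outputs have mismatched row counts")
  }
  use_labels <- strategy %in% c("labels", "labels_plus_features")
  blocks <- lapply(seq_along(base_outputs), function(b) {
    p <- base_outputs[[b]]
    if (use_labels) {
      onehot <- matrix(0, n, ncol(p))
      onehot[cbind(seq_len(n), row_argmax(p))] <- 1
      p <- onehot
    }
    cn <- colnames(base_outputs[[b]])
    if (is.null(cn)) cn <- paste0("c", seq_len(ncol(p)))
    colnames(p) <- paste0("L", b, "_", cn)
    p
  })
  out <- do.call(cbind, blocks)
  if (strategy %in% c("labels_plus_features", "probabilities_plus_features")) {
    if (is.null(original_features)) {
      stop_input("strategy '", strategy, "' requires original_features")
    }
    if (nrow(original_features) != n) {
      stop_input("original_features row count does not match base outputs")
    }
    out <- cbind(out, original_features)
  }
  out
}

#' Fit a stacked ensemble
#'
#' Normalizes the training features (zeros-mean transform fitted on this
#' training set), generates out-of-fold base-learner outputs with an internal
#' stratified k-fold so that no training row's meta feature comes from a base
#' model fitted on that row, trains the meta learner on the assembled meta
#' features, and finally refits every base learner on the full training set
#' for inference. Deterministic given `config$seed`.
#'
#' @param config A [stacking_config()].
#' @param train A [ctg_dataset()]; every class needs at least `oof_folds`
#'   instances.
#' @return An object of class `ctg_stack` holding the config, normalization
#'   parameters, fitted base and meta learners, and an `audit` record (per-row
#'   producing fold and per-fold training row indices) supporting leakage
#'   audits.
#' @export
fit_stacked <- function(config, train) {
  stopifnot(inherits(config, "ctg_stacking_config"), inherits(train, "ctg_dataset"))
  cls_n <- table(train$labels)
  if (any(cls_n < config$oof_folds)) {
    stop_config("class '", names(cls_n)[which.min(cls_n)],
                "' has fewer instances (", min(cls_n),
                ") than oof_folds (", config$oof_folds, ")")
  }
  B <- length(config$base_specs)
  k <- config$oof_folds
  seeds <- derive_seeds(config$seed, 2L + B * (k + 1L))
  split_seed <- seeds[1L]
  meta_seed <- seeds[2L]
  base_seeds <- matrix(seeds[-(1:2)], nrow = B)  # B x (k+1); last col = full refit

  norm <- fit_normalization(train$features)
  x <- suppressWarnings(apply_normalization(train$features, norm))
  n <- nrow(x)
  C <- length(train$class_names)

  split <- make_split(train$labels, "kfold", k = k, seed = split_seed)
  oof <- replicate(B, matrix(NA_real_, n, C,
                             dimnames = list(NULL, train$class_names)),
                   simplify = FALSE)
  fold_train_rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(split$assignments != f)
    te <- which(split$assignments == f)
    fold_train_rows[[f]] <- tr
    for (b in seq_len(B)) {
      spec <- config$base_specs[[b]]
      spec$seed <- base_seeds[b, f]
      m <- fit_learner(spec, x[tr, , drop = FALSE], train$labels[tr],
                       train$class_names)
      oof[[b]][te, ] <- predict(m, x[te, , drop = FALSE], type = "prob")
    }
  }
  meta_x <- build_meta_features(config$strategy, oof, x)
  meta_spec <- config$meta_spec
  meta_spec$seed <- meta_seed
  meta_fit <- fit_learner(meta_spec, meta_x, train$labels, train$class_names)

  base_fits <- lapply(seq_len(B), function(b) {
    spec <- config$base_specs[[b]]
    spec$seed <- base_seeds[b, k + 1L]
    fit_learner(spec, x, train$labels, train$class_names)
  })

  structure(list(config = config, norm = norm, base_fits = base_fits,
                 meta_fit = meta_fit, class_names = train$class_names,
                 feature_names = train$feature_names, M = ncol(x),
                 audit = list(oof_fold = split$assignments,
                              fold_train_rows = fold_train_rows)),
            class = "ctg_stack")
}

#' @export
print.ctg_stack <- function(x, ...) {
  cat("<ctg_stack> strategy=", x$config$strategy, ", ",
      length(x$base_fits), " base learners (",
      paste(vapply(x$config$base_specs, `[[`, "", "family"), collapse = ", "),
      "), meta=", x$config$meta_spec$family, "\n", sep = "")
  invisible(x)
}

#' Predict with a stacked ensemble
#'
#' Applies the stored normalization, runs every base learner, assembles the
#' meta features per the fitted strategy and returns the meta learner's
#' output. Probability rows sum to 1.
#'
#' @param object A fitted `ctg_stack`.
#' @param newdata Raw (unnormalized) feature matrix of width M.
#' @param type `"prob"` or `"class"`.
#' @param ... Unused.
#' @return Probability matrix or factor of predicted labels.
#' @export
predict.ctg_stack <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != object$M) {
    stop_input("feature count (", ncol(x), ") does not match model width (",
               object$M, ")")
  }
  colnames(x) <- object$feature_names
  xn <- suppressWarnings(apply_normalization(x, object$norm))
  base_out <- lapply(object$base_fits, predict, newdata = xn, type = "prob")
  meta_x <- build_meta_features(object$config$strategy, base_out, xn)
  predict(object$meta_fit, meta_x, type = type)
}

#' Compare the four stacking strategies under shared folds
#'
#' Runs the same cross-validation protocol once per strategy, with identical
#' fold assignments and identical seeds across strategies, and tabulates
#' accuracy and macro-F1 per strategy.
#'
#' @param dataset A [ctg_dataset()].
#' @param config A [stacking_config()]; its `strategy` field is overridden in
#'   turn by each of the four strategies.
#' @param k Cross-validation fold count (default 10).
#' @param seed Integer seed shared across the four runs.
#' @return A data frame with one row per strategy and columns `strategy`,
#'   `accuracy`, `macro_f1`; the shared `ctg_split` and the full
#'   cross-validation results are attached as attributes `"split"` and
#'   `"results"`.
#' @export
compare_strategies <- function(dataset, config = stacking_config(), k = 10,
                               seed = 1) {
  stopifnot(inherits(dataset, "ctg_dataset"))
  split <- make_split(dataset$labels, "kfold", k = k, seed = seed)
  results <- lapply(.strategies, function(s) {
    cfg <- config
    cfg$strategy <- s
    cross_validate(dataset, cfg, split = split, seed = seed)
  })
  names(results) <- .strategies
  out <- data.frame(
    strategy = .strategies,
    accuracy = vapply(results, function(r) r$average$accuracy, 0),
    macro_f1 = vapply(results, function(r) r$average$macro$f1, 0),
    row.names = NULL
  )
  attr(out, "split") <- split
  attr(out, "results") <- results
  out
}
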