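#' Specify a learner
#'
#' A uniform contract over the four learner families used by the ensemble:
#' a margin-based kernel classifier (`kernel_margin`, radial-basis SVM with
#' post-hoc probability calibration), a bagged decision-tree ensemble
#' (`bagged_trees`, probability random forest), a gradient-boosted tree
#' ensemble (`boosted_trees`) and a feed-forward network trained by error
#' backpropagation (`backprop_net`, one hidden layer, softmax output).
#' An additional `oracle` family applies a user-supplied deterministic
#' labelling rule and is intended for testing harnesses.
#'
#' @param family One of `"kernel_margin"`, `"bagged_trees"`,
#'   `"boosted_trees"`, `"backprop_net"`, `"oracle"`.
#' @param hyper Named list of hyperparameters; unknown names are rejected.
#'   Defaults: kernel_margin `cost = 1`, `kernel = "radial"`; bagged_trees
#'   `num_trees = 200`, `mtry = NULL`; boosted_trees `nrounds = 200`,
#'   `eta = 0.1`, `max_depth = 3`; backprop_net `hidden = 32`,
#'   `maxit = 500`, `decay = 1e-4`; oracle `rule` (function features ->
#'   class index or name).
#' @param seed Integer seed controlling all randomness of the fit.
#' @return An object of class `ctg_learner_spec`.
#' @export
learner_spec <- function(family = c("kernel_margin", "bagged_trees",
                                    "boosted_trees", "backprop_net", "oracle"),
                         hyper = list(), seed = 1) {
  family <- match.arg(family)
  defaults <- switch(family,
    kernel_margin = list(cost = 1, kernel = "radial", gamma = NULL,
                         class_weights = NULL),
    bagged_trees  = list(num_trees = 200, mtry = NULL, class_weights = NULL),
    boosted_trees = list(nrounds = 200, eta = 0.1, max_depth = 3),
    backprop_net  = list(hidden = 32, maxit = 500, decay = 1e-4),
    oracle        = list(rule = NULL)
  )
  unknown <- setdiff(names(hyper), names(defaults))
  if (length(unknown)) {
    stop_config("unknown hyperparameter(s) for family '", family, "': ",
                paste(unknown, collapse = ", "))
  }
  defaults[names(hyper)] <- hyper
  .validate_hyper(family, defaults)
  structure(list(family = family, hyper = defaults, seed = as.integer(seed)),
            class = "ctg_learner_spec")
}

.validate_hyper <- function(family, h) {
  chk <- function(ok, msg) if (!ok) stop_config("invalid hyperparameter: ", msg)
  switch(family,
    kernel_margin = chk(is.numeric(h$cost) && h$cost > 0, "cost must be > 0"),
    bagged_trees  = chk(is_count(h$num_trees), "num_trees must be a positive integer"),
    boosted_trees = {
      chk(is_count(h$nrounds), "nrounds must be a positive integer")
      chk(is.numeric(h$eta) && h$eta > 0 && h$eta <= 1, "eta must be in (0, 1]")
      chk(is_count(h$max_depth), "max_depth must be a positive integer")
    },
    backprop_net  = {
      chk(is_count(h$hidden), "hidden must be a positive integer")
      chk(is_count(h$maxit), "maxit must be a positive integer")
    },
    oracle = invisible(NULL)
  )
  invisible(NULL)
}

#' Fit a learner
#'
#' Fits the family named in the spec on a feature matrix and class labels.
#' Deterministic given `spec$seed`. Margin and network families expect
#' zeros-mean-normalized input (see [apply_normalization()]); tree families
#' accept raw or normalized features.
#'
#' @param spec A [learner_spec()].
#' @param features Numeric matrix (instances x M).
#' @param labels Factor (or vector coercible to one) of class labels; at
#'   least two classes must be present.
#' @param class_names Ordered class identifiers; defaults to the label
#'   levels.
#' @return An object of class `ctg_learner` with elements `spec`,
#'   `class_names`, `feature_names` and the opaque fitted state.
#' @export
fit_learner <- function(spec, features, labels, class_names = NULL) {
  stopifnot(inherits(spec, "ctg_learner_spec"))
  x <- as_feature_matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("F", seq_len(ncol(x)))
  if (is.null(class_names)) {
    class_names <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  }
  y <- factor(as.character(labels), levels = class_names)
  if (anyNA(y)) stop_input("labels contain values outside class_names")
  if (nlevels(droplevels(y)) < 2L) {
    stop_input("cannot fit on single-class labels")
  }
  h <- spec$hyper
  fit <- switch(spec$family,
    kernel_margin = withr::with_seed(spec$seed,
      e1071::svm(x = x, y = y, probability = TRUE, kernel = h$kernel,
                 cost = h$cost,
                 gamma = if (is.null(h$gamma)) 1 / ncol(x) else h$gamma,
                 class.weights = h$class_weights)),
    bagged_trees = ranger::ranger(
      x = x, y = y, probability = TRUE, num.trees = h$num_trees,
      mtry = h$mtry, seed = spec$seed, num.threads = 1,
      class.weights = h$class_weights),
    boosted_trees = withr::with_seed(spec$seed, {
      d <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(class_names),
                      eta = h$eta, max_depth = h$max_depth, nthread = 1),
        data = d, nrounds = h$nrounds, verbose = 0)
    }),
    backprop_net = withr::with_seed(spec$seed,
      nnet::nnet(x = x, y = nnet::class.ind(y), size = h$hidden,
                 softmax = TRUE, maxit = h$maxit, decay = h$decay,
                 trace = FALSE, MaxNWts = 1e6)),
    oracle = {
      if (!is.function(h$rule)) stop_config("oracle family requires a 'rule' function")
      h$rule
    }
  )
  structure(list(spec = spec, class_names = class_names,
                 feature_names = colnames(x), fit = fit),
            class = "ctg_learner")
}

#' Predict class probabilities or labels
#'
#' Probability rows are returned in `class_names` column order, clipped to
#' `[0, 1]` and renormalized so each row sums to exactly 1. Class prediction
#' is the row-wise argmax with ties broken to the lowest class index.
#'
#' @param object A fitted `ctg_learner`.
#' @param newdata Numeric matrix with the training feature width.
#' @param type `"prob"` for an n x C probability matrix, `"class"` for a
#'   factor of predicted labels.
#' @param ... Unused.
#' @return Probability matrix or factor, depending on `type`.
#' @export
predict.ctg_learner <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  if (ncol(x) != length(object$feature_names)) {
    stop_input("feature count (", ncol(x), ") does not match training width (",
               length(object$feature_names), ")")
  }
  colnames(x) <- object$feature_names
  cls <- object$class_names
  p <- switch(object$spec$family,
    kernel_margin = {
      pr <- attr(stats::predict(object$fit, x, probability = TRUE), "probabilities")
      pr[, cls, drop = FALSE]
    },
    bagged_trees = {
      pr <- stats::predict(object$fit, data = x, num.threads = 1)$predictions
      pr[, cls, drop = FALSE]
    },
    boosted_trees = {
      pr <- stats::predict(object$fit, xgboost::xgb.DMatrix(x, nthread = 1))
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = length(cls), byrow = TRUE)
      pr
    },
    backprop_net = {
      pr <- stats::predict(object$fit, x)
      if (!is.matrix(pr)) pr <- matrix(pr, ncol = length(cls))
      pr[, cls, drop = FALSE]
    },
    oracle = {
      lab <- object$fit(x)
      idx <- if (is.numeric(lab)) as.integer(lab) else match(as.character(lab), cls)
      pr <- matrix(0, nrow(x), length(cls))
      pr[cbind(seq_len(nrow(x)), idx)] <- 1
      pr
    }
  )
  p <- pmin(pmax(unname(as.matrix(p)), 0), 1)
  p <- p / rowSums(p)
  colnames(p) <- cls
  if (type == "prob") p else factor(cls[row_argmax(p)], levels = cls)
}
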