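#' Kernel SHAP configuration
#'
#' Controls the coalition enumeration/sampling, background set and solver of
#' the Kernel SHAP estimator.
#'
#' @param enum_limit Largest feature count M for exact enumeration of all
#'   `2^M - 2` interior coalitions (default 12). Beyond it, paired sampling
#'   is used.
#' @param sample_budget Number of sampled coalitions in sampling mode
#'   (default 2048; rounded down to an even count, since each draw also
#'   contributes its complement).
#' @param background_size Background (reference) rows drawn when a background
#'   is built from a training matrix (default 100).
#' @param tolerance Solver/validation tolerance (default 1e-6).
#' @param seed Integer seed for coalition sampling and background selection.
#' @param link Scale on which the model output is explained: `"identity"`
#'   (probabilities, default) or `"logit"` (log-odds).
#' @return An object of class `shap_config`.
#' @export
shap_config <- function(enum_limit = 12, sample_budget = 2048,
                        background_size = 100, tolerance = 1e-6, seed = 1,
                        link = c("identity", "logit")) {
  link <- match.arg(link)
  if (!is_count(enum_limit) || !is_count(sample_budget) || !is_count(background_size)) {
    stop_config("enum_limit, sample_budget and background_size must be positive integers")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) stop_config("tolerance must be > 0")
  structure(list(enum_limit = as.integer(enum_limit),
                 sample_budget = as.integer(sample_budget),
                 background_size = as.integer(background_size),
                 tolerance = tolerance, seed = as.integer(seed), link = link),
            class = "shap_config")
}

.apply_link <- function(p, link) {
  if (link == "identity") return(p)
  eps <- 1e-12
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' Select a background reference set
#'
#' Draws a seeded uniform subsample of rows to serve as the reference data
#' for absent features (all rows if the matrix is smaller than `size`).
#'
#' @param features Numeric matrix of candidate reference instances.
#' @param size Number of rows to keep.
#' @param seed Integer seed.
#' @return Matrix of background rows.
#' @export
shap_background <- function(features, size = 100, seed = 1) {
  x <- as_feature_matrix(features)
  if (nrow(x) <= size) return(x)
  idx <- withr::with_seed(seed, sample.int(nrow(x), size))
  x[idx, , drop = FALSE]
}

#' SHAP kernel weight for a coalition size
#'
#' The Shapley kernel `pi(z') = (M - 1) / (choose(M, s) * s * (M - s))` for a
#' coalition of `s` present features out of `M`. The boundary sizes `s = 0`
#' and `s = M` carry infinite weight and are handled as hard equality
#' constraints by the solver, not as weights.
#'
#' @param M Feature count (>= 2).
#' @param s Coalition size(s), each in `1..M-1`.
#' @return Strictly positive finite weight(s).
#' @export
shap_kernel_weight <- function(M, s) {
  if (any(s <= 0 | s >= M)) {
    stop_input("boundary coalition size (s = 0 or s = M): handled as an ",
               "equality constraint, not a kernel weight")
  }
  (M - 1) / (choose(M, s) * s * (M - s))
}

# All 2^M binary masks, row i = bits of i-1 (LSB = feature 1).
.all_masks <- function(M) {
  ints <- 0:(2^M - 1)
  vapply(seq_len(M), function(j) bitwAnd(ints, bitwShiftL(1L, j - 1L)) > 0,
         logical(length(ints))) * 1L
}

#' Build the weighted coalition system
#'
#' In exact mode (`M <= enum_limit`), enumerates all `2^M - 2` interior
#' coalitions with their Shapley kernel weights. In sampling mode, draws
#' coalition sizes from the distribution the kernel implies over sizes and
#' emits each sampled mask together with its complement, accumulating repeat
#' draws as integer multiplicities that serve as regression weights.
#' Deterministic given `config$seed`.
#'
#' @param M Feature count (>= 2).
#' @param config A [shap_config()].
#' @return List with `masks` (L x M 0/1 matrix), `weights` (length L) and
#'   `mode` (`"exact"` or `"sampled"`).
#' @export
build_coalition_system <- function(M, config = shap_config()) {
  if (!is_count(M) || M < 2) stop_input("M must be an integer >= 2")
  if (M <= config$enum_limit) {
    masks <- .all_masks(M)
    masks <- masks[-c(1L, nrow(masks)), , drop = FALSE]
    return(list(masks = masks, weights = shap_kernel_weight(M, rowSums(masks)),
                mode = "exact"))
  }
  draws <- max(1L, config$sample_budget %/% 2L)
  sizes <- seq_len(M - 1L)
  # kernel weight x number of masks of that size: p(s) proportional to 1/(s(M-s))
  psize <- 1 / (sizes * (M - sizes))
  keys <- withr::with_seed(config$seed, {
    s_draw <- sample(sizes, draws, replace = TRUE, prob = psize)
    vapply(s_draw, function(s) {
      bits <- integer(M)
      bits[sample.int(M, s)] <- 1L
      paste(bits, collapse = "")
    }, "")
  })
  comp <- chartr("01", "10", keys)
  tab <- table(c(keys, comp))
  masks <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  list(masks = masks, weights = as.numeric(tab), mode = "sampled")
}

# Evaluate the value function v(z) for each mask: mean over background rows of
# f(hybrid), where the hybrid takes x where the mask is 1 and the background
# row where it is 0. Returns an L x C matrix (one column per model output).
.masked_values <- function(f, x, masks, background) {
  nb <- nrow(background)
  L <- nrow(masks)
  big <- background[rep(seq_len(nb), times = L), , drop = FALSE]
  maskrep <- masks[rep(seq_len(L), each = nb), , drop = FALSE]
  xrep <- matrix(x, nrow(big), length(x), byrow = TRUE)
  big[maskrep == 1] <- xrep[maskrep == 1]
  out <- f(big)
  if (!is.matrix(out)) out <- matrix(out, ncol = 1L)
  rowsum(out, group = rep(seq_len(L), each = nb)) / nb
}

#' Masked model evaluation
#'
#' Expected model output for a feature coalition: features present in the
#' mask keep the explained instance's values, absent features are replaced by
#' each background row in turn (interventional hybrid rows), and the model's
#' outputs are averaged over the background.
#'
#' @param f Prediction function mapping a feature matrix to an output matrix
#'   (one column per class) or vector.
#' @param x Explained instance (numeric vector of length M).
#' @param mask 0/1 coalition vector of length M.
#' @param background Background matrix (rows x M).
#' @param class_index Optional column to extract; otherwise all outputs.
#' @return Numeric vector of expected outputs (or scalar if `class_index`).
#' @export
masked_prediction <- function(f, x, mask, background, class_index = NULL) {
  background <- as_feature_matrix(background)
  if (!nrow(background)) stop_config("background set is empty")
  if (length(x) != ncol(background) || length(mask) != length(x)) {
    stop_input("x, mask and background widths must agree")
  }
  v <- .masked_values(f, x, matrix(mask, nrow = 1L), background)[1L, ]
  if (is.null(class_index)) v else v[[class_index]]
}

#' Solve the kernel-weighted Shapley regression
#'
#' Minimizes the kernel-weighted squared loss between the additive
#' explanation `g(z') = phi0 + sum_i phi_i z'_i` and the masked model values,
#' subject to the two boundary constraints `g(empty) = phi0` and
#' `g(full) = f(x)`. The full-coalition constraint is enforced exactly by
#' eliminating the last unknown (`phi_M = fx - phi0 - sum_{i<M} phi_i`), so
#' local accuracy holds by construction.
#'
#' @param masks L x M 0/1 matrix of interior coalitions.
#' @param weights Positive kernel weights (length L).
#' @param values Masked model values `v(z)` per coalition (length L).
#' @param base_value `phi0`, the expected output over the background.
#' @param fx Model output at the explained instance.
#' @param tolerance Reciprocal-condition threshold below which the normal
#'   equations are declared rank-deficient.
#' @return Numeric vector `phi_1..phi_M`.
#' @export
solve_shap_regression <- function(masks, weights, values, base_value, fx,
                                  tolerance = 1e-10) {
  if (!nrow(masks)) stop_input("empty coalition system")
  if (!is.finite(base_value) || !is.finite(fx)) stop_input("base_value and fx must be finite")
  M <- ncol(masks)
  zM <- masks[, M]
  y <- values - base_value - zM * (fx - base_value)
  X <- masks[, -M, drop = FALSE] - zM
  A <- crossprod(X, X * weights)
  b <- crossprod(X, y * weights)
  if (rcond(A) < tolerance) {
    stop(errorCondition(
      paste0("rank-deficient coalition system (rcond = ",
             format(rcond(A)), "); increase the sample budget or use exact mode"),
      class = c("ctg_numerical_error", "error")))
  }
  phi <- drop(solve(A, b))
  c(phi, fx - base_value - sum(phi))
}

# Shared core: system + masked values -> one explanation per output column.
.explain_core <- function(fl, x, background, system, feature_names, class_names) {
  vals <- .masked_values(fl, x, system$masks, background)
  phi0 <- colMeans(fl(background))
  fx <- .masked_values(fl, x, matrix(1L, 1L, length(x)), background)[1L, ]
  C <- ncol(vals)
  lapply(seq_len(C), function(cl) {
    phi <- solve_shap_regression(system$masks, system$weights, vals[, cl],
                                 phi0[cl], fx[cl])
    names(phi) <- feature_names
    structure(list(class_index = cl,
                   class_name = if (!is.null(class_names)) class_names[cl] else paste0("class", cl),
                   base_value = unname(phi0[cl]), shap_values = phi,
                   fx = unname(fx[cl]), feature_values = stats::setNames(x, feature_names),
                   mode = system$mode),
              class = "shap_explanation")
  })
}

#' Explain one instance with Kernel SHAP
#'
#' Produces one additive explanation per model output class: the base value
#' `phi0` (expected output over the background), per-feature Shapley values
#' `phi_i`, and the model output `f(x)`, satisfying local accuracy
#' `phi0 + sum_i phi_i = f(x)`.
#'
#' @param f Prediction function (matrix -> per-class output matrix), e.g.
#'   from [predict_function()].
#' @param x Explained instance: numeric vector of length M.
#' @param background Background matrix (see [shap_background()]).
#' @param config A [shap_config()].
#' @param class_names Optional class identifiers for labelling.
#' @param feature_names Optional feature names; default taken from the
#'   background columns.
#' @return List of `shap_explanation` objects, one per class.
#' @export
explain_instance <- function(f, x, background, config = shap_config(),
                             class_names = NULL, feature_names = NULL) {
  background <- as_feature_matrix(background)
  x <- as.numeric(x)
  if (length(x) != ncol(background)) stop_input("x width must match background width")
  if (is.null(feature_names)) feature_names <- colnames(background)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_along(x))
  fl <- function(m) .apply_link({
    out <- f(m); if (!is.matrix(out)) matrix(out, ncol = 1L) else out
  }, config$link)
  system <- build_coalition_system(length(x), config)
  .explain_core(fl, x, background, system, feature_names, class_names)
}

#' Explain many instances, reusing one coalition system
#'
#' @param f Prediction function.
#' @param X Matrix of instances to explain (rows).
#' @param background Background matrix.
#' @param config A [shap_config()].
#' @param class_names Optional class identifiers.
#' @return List (one element per row of `X`) of per-class explanation lists.
#' @export
explain_instances <- function(f, X, background, config = shap_config(),
                              class_names = NULL) {
  X <- as_feature_matrix(X)
  background <- as_feature_matrix(background)
  feature_names <- colnames(background)
  if (is.null(feature_names)) feature_names <- paste0("F", seq_len(ncol(X)))
  fl <- function(m) .apply_link({
    out <- f(m); if (!is.matrix(out)) matrix(out, ncol = 1L) else out
  }, config$link)
  system <- build_coalition_system(ncol(X), config)
  lapply(seq_len(nrow(X)), function(i) {
    .explain_core(fl, X[i, ], background, system, feature_names, class_names)
  })
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> class %s: f(x)=%.4f base=%.4f (%s mode)\n",
              x$class_name, x$fx, x$base_value, x$mode))
  top <- sort(abs(x$shap_values), decreasing = TRUE)
  show <- utils::head(names(top), 5L)
  for (f in show) cat(sprintf("  %-10s phi=%+.4f\n", f, x$shap_values[[f]]))
  invisible(x)
}

#' Wrap a fitted model as a prediction function
#'
#' Returns a closure mapping a raw feature matrix to the model's class
#' probability matrix, suitable for [explain_instance()] and
#' [exact_shapley_oracle()]. Stacked ensembles apply their stored
#' normalization internally, so explanations are in original feature units.
#'
#' @param model A `ctg_learner` or `ctg_stack`.
#' @return Function: matrix -> n x C probability matrix.
#' @export
predict_function <- function(model) {
  stopifnot(inherits(model, "ctg_learner") || inherits(model, "ctg_stack"))
  function(m) predict(model, m, type = "prob")
}

#' Exact brute-force Shapley values
#'
#' Enumerates all `2^M` coalitions and computes each feature's Shapley value
#' as its average marginal contribution,
#' `phi_i = sum_{S not containing i} |S|! (M-|S|-1)! / M! * (v(S u {i}) - v(S))`,
#' with `v(S)` the interventional masked prediction over the background.
#' Exponential cost; intended as the validation oracle for the kernel
#' estimator.
#'
#' @param f Prediction function.
#' @param x Explained instance (length M <= 10).
#' @param background Background matrix.
#' @param class_index Model output column to explain (default 1).
#' @param link As in [shap_config()].
#' @return Numeric vector `phi_1..phi_M`, named by background columns.
#' @export
exact_shapley_oracle <- function(f, x, background, class_index = 1,
                                 link = "identity") {
  background <- as_feature_matrix(background)
  x <- as.numeric(x)
  M <- length(x)
  if (M > 10) stop_input("brute-force oracle limited to M <= 10 (cost 2^M)")
  if (M != ncol(background)) stop_input("x width must match background width")
  fl <- function(m) .apply_link({
    out <- f(m); if (!is.matrix(out)) matrix(out, ncol = 1L) else out
  }, link)
  masks <- .all_masks(M)
  v <- .masked_values(fl, x, masks, background)[, class_index]
  sizes <- rowSums(masks)
  # weight |S|!(M-|S|-1)!/M!; the full mask never serves as S (no feature absent)
  w <- ifelse(sizes < M,
              factorial(sizes) * factorial(pmax(M - sizes - 1, 0)) / factorial(M), 0)
  phi <- numeric(M)
  for (i in seq_len(M)) {
    without <- masks[, i] == 0L
    idx <- which(without)
    idx_with <- idx + 2^(i - 1L)  # adding feature i flips bit i-1
    phi[i] <- sum(w[idx] * (v[idx_with] - v[idx]))
  }
  stats::setNames(phi, colnames(background))
}
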