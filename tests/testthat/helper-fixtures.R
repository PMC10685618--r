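# Shared fixtures: lightweight learner settings and small generated datasets.

fast_base_specs <- function(seed = 1) {
  list(learner_spec("kernel_margin", seed = seed),
       learner_spec("boosted_trees", list(nrounds = 40), seed = seed + 1L),
       learner_spec("bagged_trees", list(num_trees = 50), seed = seed + 2L))
}

fast_meta_spec <- function(seed = 1) {
  learner_spec("backprop_net", list(hidden = 8, maxit = 200), seed = seed)
}

fast_stack_config <- function(strategy = "probabilities_plus_features",
                              oof_folds = 3, seed = 1) {
  stacking_config(fast_base_specs(seed), fast_meta_spec(seed),
                  strategy = strategy, oof_folds = oof_folds, seed = seed)
}

# Two well-separated Gaussian clusters at +/- 3 along the first feature:
# linearly separable with a wide margin, and the sign of feature 1 survives
# z-normalization.
separable_toy <- function(n_per_class = 10, M = 3, seed = 1) {
  withr::with_seed(seed, {
    n <- 2L * n_per_class
    x <- matrix(rnorm(n * M, sd = 0.2), n, M)
    x[, 1] <- x[, 1] + rep(c(3, -3), each = n_per_class)
    colnames(x) <- paste0("F", seq_len(M))
    ctg_dataset(x, rep(c("A", "B"), each = n_per_class), class_names = c("A", "B"))
  })
}

small_synthetic <- function(n_per_class = c(N = 120, S = 40, P = 30), seed = 1) {
  generate_synthetic(synthetic_spec(n_per_class = n_per_class, seed = seed))
}

# A tree-ensemble probability model on a small 2-class dataset with M
# features, for SHAP checks.
shap_test_model <- function(M, seed = 1) {
  drivers <- stats::setNames(list(c(0, 1.5), c(0, -1.2)),
                             paste0("F", c(1L, min(2L, M))))
  ds <- generate_synthetic(synthetic_spec(
    n_per_class = c(A = 45, B = 30), M = M,
    feature_names = paste0("F", seq_len(M)),
    drivers = drivers, seed = seed))
  model <- fit_learner(learner_spec("bagged_trees", list(num_trees = 30),
                                    seed = seed + 1L),
                       ds$features, ds$labels, ds$class_names)
  list(dataset = ds, model = model, f = predict_function(model))
}
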