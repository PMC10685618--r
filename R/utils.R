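# Internal helpers: classed errors, seed fan-out, small validators.

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctg_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ctg_input_error", "error")))
}

#' @noRd
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x) && x >= 1
}

# Deterministically fan one integer seed out to n sub-seeds without touching
# global RNG state outside the call.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

as_feature_matrix <- function(x, feature_names = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_input("features must be a numeric matrix or data frame")
  }
  if (!is.null(feature_names)) colnames(x) <- feature_names
  x
}

# Row-wise argmax with ties broken to the lowest index.
row_argmax <- function(p) {
  max.col(p, ties.method = "first")
}
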