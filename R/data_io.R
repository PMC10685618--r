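#' Construct a CTG dataset object
#'
#' Bundles a numeric feature matrix with per-instance class labels. This is the
#' container every fitting, evaluation and explanation function in the package
#' consumes.
#'
#' @param features Numeric matrix (instances x features) or data frame of
#'   continuous feature values.
#' @param labels Class label per instance: a factor, a character vector of
#'   class names, or integer codes indexing `class_names` (1-based).
#' @param class_names Ordered character vector of class identifiers (e.g.
#'   `c("N", "S", "P")`). Defaults to the label levels in order of appearance.
#' @param feature_names Optional character vector of unique feature names;
#'   defaults to the column names of `features`.
#'
#' @return An object of class `ctg_dataset`: a list with elements `features`
#'   (matrix), `labels` (factor with levels `class_names`), `feature_names`
#'   and `class_names`.
#' @export
ctg_dataset <- function(features, labels, class_names = NULL, feature_names = NULL) {
  features <- as_feature_matrix(features, feature_names)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("F", seq_len(ncol(features)))
  }
  feature_names <- colnames(features)
  if (anyDuplicated(feature_names)) stop_input("feature names must be unique")
  if (ncol(features) < 2L) stop_input("a dataset needs at least 2 features")

  if (is.null(class_names)) {
    class_names <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
  }
  if (length(class_names) < 2L) stop_input("a dataset needs at least 2 classes")
  if (is.numeric(labels)) {
    if (any(labels < 1 | labels > length(class_names))) {
      stop_input("integer labels must index class_names")
    }
    labels <- factor(class_names[labels], levels = class_names)
  } else {
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), class_names)
    if (length(bad)) {
      stop_input("unknown label value(s): ", paste(bad, collapse = ", "))
    }
    labels <- factor(labels, levels = class_names)
  }
  if (length(labels) != nrow(features)) {
    stop_input("length of labels (", length(labels), ") must equal number of rows (",
               nrow(features), ")")
  }
  structure(
    list(features = features, labels = labels,
         feature_names = feature_names, class_names = class_names),
    class = "ctg_dataset"
  )
}

#' @export
print.ctg_dataset <- function(x, ...) {
  cat("<ctg_dataset> ", nrow(x$features), " instances, ", ncol(x$features),
      " features, ", length(x$class_names), " classes\n", sep = "")
  cat("  classes:", paste(sprintf("%s=%d", x$class_names, as.integer(table(x$labels))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CTG dataset by row
#' @param dataset A `ctg_dataset`.
#' @param idx Row indices (integer or logical).
#' @return A `ctg_dataset` restricted to the selected instances.
#' @export
dataset_subset <- function(dataset, idx) {
  ctg_dataset(dataset$features[idx, , drop = FALSE],
              dataset$labels[idx],
              class_names = dataset$class_names)
}

# Column-name aliases seen in common UCI cardiotocography CSV exports.
.ctg_column_aliases <- c(LBE = "LB", Class = "NSP", CLASS = "NSP")

#' Load a CTG feature table from CSV
#'
#' Reads a comma-delimited text table with a header row, one label column and
#' numeric feature columns, in the layout of a UCI cardiotocography CSV export
#' (21 features plus the NSP fetal-state label). A small alias map translates
#' common export variants of the column names (e.g. `LBE` for `LB`).
#'
#' @param path Path to the CSV file.
#' @param label_column Name of the label column (default `"NSP"`).
#' @param class_names Ordered class identifiers. Numeric label values are
#'   interpreted as 1-based indices into this vector (the UCI NSP coding
#'   1/2/3 maps to N/S/P); string values must match it.
#' @param aliases Named character vector mapping export column names to
#'   canonical ones; merged over the built-in alias map.
#'
#' @return A [ctg_dataset()] with features in header order (label column
#'   excluded) and row order preserved.
#' @export
load_ctg_csv <- function(path, label_column = "NSP",
                         class_names = c("N", "S", "P"),
                         aliases = character()) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  amap <- c(aliases, .ctg_column_aliases)
  hit <- names(raw) %in% names(amap)
  names(raw)[hit] <- unname(amap[names(raw)[hit]])
  if (!label_column %in% names(raw)) {
    stop_config("label column '", label_column, "' not found; columns are: ",
                paste(names(raw), collapse = ", "))
  }
  lab_raw <- raw[[label_column]]
  feat <- raw[setdiff(names(raw), label_column)]
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        bad <- which(is.na(num))[1L]
        stop_input("non-numeric value in column '", names(feat)[j],
                   "', row ", bad, ": '", v[bad], "'")
      }
      feat[[j]] <- num
    }
  }
  if (is.numeric(lab_raw)) {
    if (any(lab_raw < 1 | lab_raw > length(class_names) | lab_raw != floor(lab_raw))) {
      stop_input("numeric label outside 1..", length(class_names),
                 " in column '", label_column, "'")
    }
  }
  ctg_dataset(as.matrix(feat), lab_raw, class_names = class_names)
}

#' Write a CTG dataset to CSV
#'
#' Writes features at full double precision (`%.17g`) so that a write/load
#' round trip reproduces the matrix bit for bit; the label column holds class
#' names.
#'
#' @param dataset A `ctg_dataset`.
#' @param path Output file path.
#' @param label_column Name for the label column (default `"NSP"`).
#' @return Invisibly, `path`.
#' @export
write_ctg_csv <- function(dataset, path, label_column = "NSP") {
  feat <- dataset$features
  txt <- apply(feat, 2, function(col) sprintf("%.17g", col))
  if (nrow(feat) == 1L) txt <- matrix(txt, nrow = 1L)
  df <- as.data.frame(txt, stringsAsFactors = FALSE)
  names(df) <- dataset$feature_names
  df[[label_column]] <- as.character(dataset$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit zeros-mean normalization parameters
#'
#' Computes the per-feature mean and standard deviation used by the
#' zeros-mean (z-score) transform `(x - mu) / sigma`. The standard deviation
#' is the population form (divide by n) by default.
#'
#' @param train_features Numeric matrix of training instances.
#' @param sample_sd If `TRUE`, use the sample (divide by n-1) standard
#'   deviation instead of the population form.
#' @return An object of class `ctg_norm`: list with `mu`, `sigma`,
#'   `fitted_on` (row count) and `sample_sd`.
#' @export
fit_normalization <- function(train_features, sample_sd = FALSE) {
  x <- as_feature_matrix(train_features)
  if (nrow(x) < 2L) stop_input("need at least 2 instances to fit normalization")
  mu <- colMeans(x)
  ctr <- sweep(x, 2, mu)
  denom <- if (sample_sd) nrow(x) - 1L else nrow(x)
  sigma <- sqrt(colSums(ctr^2) / denom)
  structure(list(mu = mu, sigma = sigma, fitted_on = nrow(x),
                 sample_sd = sample_sd),
            class = "ctg_norm")
}

#' Apply zeros-mean normalization
#'
#' Transforms each cell to `(x - mu) / sigma` with previously fitted
#' parameters. Constant features (sigma = 0) map to 0 with a warning, keeping
#' them inert rather than producing NaN.
#'
#' @param features Numeric matrix with the same column count the params were
#'   fitted on.
#' @param params A `ctg_norm` object from [fit_normalization()].
#' @return The normalized matrix.
#' @export
apply_normalization <- function(features, params) {
  x <- as_feature_matrix(features)
  if (ncol(x) != length(params$mu)) {
    stop_input("feature count (", ncol(x), ") does not match normalization params (",
               length(params$mu), ")")
  }
  zero <- params$sigma == 0
  sigma <- ifelse(zero, 1, params$sigma)
  out <- sweep(sweep(x, 2, params$mu), 2, sigma, "/")
  if (any(zero)) {
    out[, zero] <- 0
    warning("constant feature(s) mapped to 0 under normalization: ",
            paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  }
  out
}

#' Create a stratified split plan
#'
#' Builds either a k-fold cross-validation assignment or a train/test hold-out
#' partition, optionally stratified so each fold's per-class count stays
#' within one instance of the proportional share. Deterministic for a fixed
#' seed.
#'
#' @param labels Factor (or vector) of class labels, one per instance.
#' @param mode `"kfold"` or `"holdout"`.
#' @param k Number of folds (kfold mode).
#' @param fraction Training fraction in (0, 1) (holdout mode; default 0.7).
#' @param stratified Stratify by class (default `TRUE`).
#' @param seed Integer seed.
#' @return An object of class `ctg_split`: list with `mode`, `assignments`
#'   (fold index per instance, or `"train"`/`"test"`), `k` or `fraction`,
#'   `stratified` and `seed`. Serializable to JSON with
#'   [jsonlite::write_json()].
#' @export
make_split <- function(labels, mode = c("kfold", "holdout"), k = 10,
                       fraction = 0.7, stratified = TRUE, seed = 1) {
  mode <- match.arg(mode)
  labels <- as.factor(labels)
  n <- length(labels)
  assignments <- if (mode == "kfold") {
    if (!is_count(k) || k < 2) stop_config("k must be an integer >= 2")
    if (k > n) stop_config("k (", k, ") exceeds instance count (", n, ")")
    k <- as.integer(k)
    fold <- integer(n)
    withr::with_seed(seed, {
      if (stratified) {
        # round-robin continues across classes so global fold sizes stay
        # within one of each other as well
        offset <- 0L
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          fold[sample(idx)] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
          offset <- (offset + length(idx)) %% k
        }
      } else {
        fold <- sample(rep_len(seq_len(k), n))
      }
    })
    fold
  } else {
    if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
      stop_config("fraction must be in (0, 1)")
    }
    is_train <- logical(n)
    withr::with_seed(seed, {
      if (stratified) {
        for (cl in levels(labels)) {
          idx <- which(labels == cl)
          is_train[sample(idx, round(fraction * length(idx)))] <- TRUE
        }
      } else {
        is_train[sample(n, round(fraction * n))] <- TRUE
      }
    })
    ifelse(is_train, "train", "test")
  }
  structure(list(mode = mode, assignments = assignments,
                 k = if (mode == "kfold") as.integer(k) else NULL,
                 fraction = if (mode == "holdout") fraction else NULL,
                 stratified = stratified, seed = as.integer(seed)),
            class = "ctg_split")
}

# ---------------------------------------------------------------------------
# Synthetic CTG-like data

.public_feature_names <- c(
  "LB", "AC", "FM", "UC", "DL", "DS", "DP", "ASTV", "MSTV", "ALTV", "MLTV",
  "Width", "Min", "Max", "Nmax", "Nzeros", "Mode", "Mean", "Median",
  "Variance", "Tendency"
)

.private_feature_names <- c(
  "LB", "AC", "AA", "AD", "STV", "SD", "VA", "VD", "LD1", "LD2", "ED",
  "DVHF", "DAD", "DVD", "DUC", "DVLF", "DC", "DL", "PD", "PV", "TUC",
  "IUC", "UC", "FM", "GA", "AGE"
)

# Default per-class mean shifts (standardized units) for the class-driving
# features of the public-like generator: abnormal states raise ASTV/ALTV/DP
# and lower AC/Mean, with ASTV the strongest pathologic driver.
.public_drivers <- list(
  ASTV = c(0,  1.4,  3.0),
  ALTV = c(0,  1.2,  1.4),
  AC   = c(0, -1.2, -1.6),
  Mean = c(0, -0.8, -1.2),
  DP   = c(0,  0.2,  1.2)
)

.private_drivers <- list(
  AC  = c(0, -1.6),
  AD  = c(0, -1.2),
  STV = c(0, -1.0)
)

#' Specify a synthetic CTG-like dataset
#'
#' Describes a generator that emulates the structure of a public
#' cardiotocography feature table: imbalanced classes, ~21 continuous
#' features on a standardized scale, and a small set of "driver" features
#' whose class-conditional means shift in clinically plausible directions
#' (abnormal states raise ASTV, ALTV and DP and lower AC and the histogram
#' Mean). Non-driver features are class-independent noise.
#'
#' @param n_per_class Integer vector of class sizes; defaults to the
#'   1655/295/176 N/S/P imbalance of the public dataset.
#' @param M Feature count (default 21).
#' @param class_names Class identifiers; default `c("N","S","P")`.
#' @param feature_names Feature names; defaults to the public CTG attribute
#'   symbols.
#' @param drivers Named list: feature name -> numeric vector of per-class
#'   mean shifts (length = number of classes), in units of `noise_scale`.
#' @param noise_scale Standard deviation of every feature around its
#'   class-conditional mean (default 1).
#' @param seed Integer seed; identical specs with identical seeds generate
#'   identical datasets.
#' @return An object of class `ctg_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(N = 1655, S = 295, P = 176),
                           M = 21,
                           class_names = NULL,
                           feature_names = NULL,
                           drivers = NULL,
                           noise_scale = 1,
                           seed = 1) {
  C <- length(n_per_class)
  if (C < 2L) stop_config("need at least 2 classes")
  if (any(n_per_class < 1)) stop_config("all class sizes must be >= 1")
  if (is.null(class_names)) {
    class_names <- if (!is.null(names(n_per_class))) names(n_per_class)
                   else paste0("C", seq_len(C))
  }
  if (is.null(feature_names)) {
    base <- if (M == 26L) .private_feature_names else .public_feature_names
    feature_names <- if (M <= length(base)) base[seq_len(M)]
                     else c(base, paste0("X", seq_len(M - length(base))))
  }
  if (length(feature_names) != M) stop_config("feature_names must have length M")
  if (is.null(drivers)) {
    pool <- if (C == 2L) .private_drivers else .public_drivers
    drivers <- lapply(pool[names(pool) %in% feature_names], function(s) {
      if (length(s) == C) s else c(0, rep_len(s[-1], C - 1L))
    })
  }
  if (!length(drivers)) stop_config("at least one driver feature is required")
  if (length(drivers) > M) stop_config("more drivers than features (M = ", M, ")")
  bad <- setdiff(names(drivers), feature_names)
  if (length(bad)) stop_config("driver feature(s) not in feature_names: ",
                               paste(bad, collapse = ", "))
  if (any(lengths(drivers) != C)) {
    stop_config("each driver shift vector must have one entry per class")
  }
  structure(list(n_per_class = as.integer(n_per_class), M = as.integer(M),
                 class_names = class_names, feature_names = feature_names,
                 drivers = drivers, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "ctg_synthetic_spec")
}

#' Specify a private-hospital-like 2-class synthetic dataset
#'
#' Convenience wrapper around [synthetic_spec()] emulating a 2-class
#' (normal/abnormal) feature table with 26 attributes, where low
#' accelerations (AC), short acceleration duration (AD) and low short-term
#' variability (STV) drive the abnormal class.
#'
#' @param n_per_class Class sizes (default 11998/4357 normal/abnormal).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [synthetic_spec()].
#' @return A `ctg_synthetic_spec`.
#' @export
synthetic_private_spec <- function(n_per_class = c(Normal = 11998, Abnormal = 4357),
                                   seed = 1, ...) {
  synthetic_spec(n_per_class = n_per_class, M = 26,
                 feature_names = .private_feature_names,
                 drivers = .private_drivers, seed = seed, ...)
}

#' Generate a synthetic CTG-like dataset
#'
#' Draws the dataset described by a [synthetic_spec()]: every feature is
#' Gaussian with standard deviation `noise_scale`; driver features get their
#' per-class mean shifts, all other features are class-independent.
#' Reproducible from the spec's seed.
#'
#' @param spec A `ctg_synthetic_spec`.
#' @return A [ctg_dataset()] with exactly the requested class sizes, in class
#'   block order.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "ctg_synthetic_spec"))
  n <- sum(spec$n_per_class)
  C <- length(spec$n_per_class)
  labels <- rep(seq_len(C), spec$n_per_class)
  shift <- matrix(0, C, spec$M, dimnames = list(NULL, spec$feature_names))
  for (f in names(spec$drivers)) shift[, f] <- spec$drivers[[f]] * spec$noise_scale
  x <- withr::with_seed(spec$seed,
    matrix(stats::rnorm(n * spec$M, sd = spec$noise_scale), n, spec$M)
  )
  x <- x + shift[labels, , drop = FALSE]
  colnames(x) <- spec$feature_names
  ctg_dataset(x, labels, class_names = spec$class_names)
}
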