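test_that("dataset construction validates invariants and maps labels", {
  x <- matrix(1:12, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  ds <- ctg_dataset(x, c(1, 2, 1, 2), class_names = c("lo", "hi"))
  expect_s3_class(ds, "ctg_dataset")
  expect_identical(levels(ds$labels), c("lo", "hi"))
  expect_identical(as.character(ds$labels), c("lo", "hi", "lo", "hi"))

  expect_error(ctg_dataset(x, c(1, 2, 1)), class = "ctg_input_error")
  expect_error(ctg_dataset(x, c(1, 3, 1, 2), class_names = c("lo", "hi")),
               class = "ctg_input_error")
  expect_error(ctg_dataset(x, c("lo", "xx", "lo", "hi"), class_names = c("lo", "hi")),
               class = "ctg_input_error")
  colnames(x) <- c("a", "a", "c")
  expect_error(ctg_dataset(x, c(1, 2, 1, 2), class_names = c("lo", "hi")),
               class = "ctg_input_error")
  expect_error(ctg_dataset(matrix(1:4, 4, 1), c(1, 2, 1, 2),
                           class_names = c("lo", "hi")),
               class = "ctg_input_error")
})

test_that("CSV write/load round trip is bit-exact and order preserving", {
  ds <- small_synthetic(seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ctg_csv(ds, path)
  back <- load_ctg_csv(path, class_names = ds$class_names)
  expect_identical(unname(back$features), unname(ds$features))
  expect_identical(back$labels, ds$labels)
  expect_identical(back$feature_names, ds$feature_names)

  # 2-row toy with 3 features and a binary label reads back identically
  toy <- ctg_dataset(matrix(c(0.1, -2.5, 3.25, 1e-9, 7, 0), 2, 3,
                            dimnames = list(NULL, c("u", "v", "w"))),
                     c("yes", "no"), class_names = c("no", "yes"))
  write_ctg_csv(toy, path, label_column = "outcome")
  back <- load_ctg_csv(path, label_column = "outcome", class_names = c("no", "yes"))
  expect_identical(unname(back$features), unname(toy$features))
  expect_identical(back$labels, toy$labels)
})

test_that("loader reports configuration, parse and labeling errors; aliases apply", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("LBE,AC,NSP", "120,0.1,1", "130,0.2,2"), path)
  ds <- load_ctg_csv(path, class_names = c("N", "S", "P"))
  expect_identical(ds$feature_names, c("LB", "AC"))  # alias resolved

  expect_error(load_ctg_csv(path, label_column = "Missing"),
               class = "ctg_config_error")

  writeLines(c("a,b,NSP", "1,x,1", "2,3,2"), path)
  err <- tryCatch(load_ctg_csv(path), condition = identity)
  expect_s3_class(err, "ctg_input_error")
  expect_match(conditionMessage(err), "column 'b'")
  expect_match(conditionMessage(err), "row 1")

  writeLines(c("a,b,NSP", "1,2,9", "2,3,2"), path)
  expect_error(load_ctg_csv(path), class = "ctg_input_error")
})

test_that("normalization matches column statistics and guards sigma = 0", {
  p <- fit_normalization(cbind(a = c(0, 2), b = c(5, 5)))
  expect_equal(unname(p$mu), c(1, 5))
  expect_equal(unname(p$sigma), c(1, 0))

  # brute-force recomputation oracle on a random matrix
  x <- withr::with_seed(5, matrix(rnorm(400), 100, 4))
  p <- fit_normalization(x)
  mu_oracle <- apply(x, 2, function(col) sum(col) / length(col))
  sd_oracle <- apply(x, 2, function(col) sqrt(sum((col - mean(col))^2) / length(col)))
  expect_equal(unname(p$mu), mu_oracle, tolerance = 1e-12)
  expect_equal(unname(p$sigma), sd_oracle, tolerance = 1e-12)

  z <- apply_normalization(x, p)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_equal(unname(apply(z, 2, function(c) sqrt(mean((c - mean(c))^2)))),
               rep(1, 4), tolerance = 1e-12)

  # sample-sd switch
  ps <- fit_normalization(x, sample_sd = TRUE)
  expect_equal(unname(ps$sigma), unname(apply(x, 2, sd)), tolerance = 1e-12)

  # constant column maps to zero with a warning; new instance substitution
  pc <- fit_normalization(cbind(k = c(5, 5, 5), v = c(0, 1, 2)))
  expect_warning(zc <- apply_normalization(cbind(k = 7, v = 3), pc),
                 "constant")
  expect_identical(unname(zc[1, 1]), 0)
  expect_equal(unname(zc[1, 2]), (3 - 1) / sqrt(2 / 3))

  expect_error(apply_normalization(x[, 1:2], p), class = "ctg_input_error")
  expect_error(fit_normalization(x[1, , drop = FALSE]), class = "ctg_input_error")
})

test_that("k-fold splits partition instances with per-class balance", {
  labels <- factor(rep(c("a", "b"), each = 5))
  sp <- make_split(labels, "kfold", k = 10, seed = 3)
  expect_identical(sort(unique(sp$assignments)), 1:10)
  expect_true(all(table(sp$assignments) == 1))  # leave-one-out structure

  # property: union = all, disjoint, per-fold class counts within 1 of share
  for (seed in 1:5) {
    n_cl <- withr::with_seed(seed, sample(5:40, 3))
    labels <- factor(rep(c("x", "y", "z"), n_cl))
    k <- withr::with_seed(seed + 100, sample(2:5, 1))
    sp <- make_split(labels, "kfold", k = k, seed = seed)
    expect_length(sp$assignments, sum(n_cl))
    expect_true(all(sp$assignments %in% seq_len(k)))
    tab <- table(factor(sp$assignments, levels = seq_len(k)), labels)
    share <- matrix(n_cl / k, k, 3, byrow = TRUE)
    expect_true(all(abs(tab - share) <= 1))
  }

  expect_identical(make_split(labels, "kfold", k = 4, seed = 9)$assignments,
                   make_split(labels, "kfold", k = 4, seed = 9)$assignments)
  expect_error(make_split(labels[1:3], "kfold", k = 5), class = "ctg_config_error")
})

test_that("stratified holdout reproduces the 70/30 class arithmetic", {
  labels <- factor(rep(c("N", "S", "P"), c(1655, 295, 176)),
                   levels = c("N", "S", "P"))
  sp <- make_split(labels, "holdout", fraction = 0.7, seed = 4)
  tr <- table(labels[sp$assignments == "train"])
  expect_true(all(abs(tr - c(1159, 206, 123)) <= 1))
  expect_identical(sum(sp$assignments == "train") + sum(sp$assignments == "test"),
                   2126L)
  expect_error(make_split(labels, "holdout", fraction = 1.2),
               class = "ctg_config_error")
})

test_that("synthetic generator honors sizes, seed and driver directions", {
  spec <- synthetic_spec(n_per_class = c(N = 50, S = 10, P = 6), seed = 21)
  ds <- generate_synthetic(spec)
  expect_identical(as.integer(table(ds$labels)), c(50L, 10L, 6L))
  expect_identical(ncol(ds$features), 21L)

  ds2 <- generate_synthetic(spec)
  expect_identical(ds$features, ds2$features)

  # driver marginal means move in the configured directions (n >= 50/class)
  big <- generate_synthetic(synthetic_spec(n_per_class = c(N = 200, S = 80, P = 60),
                                           seed = 22))
  mn <- function(f, cl) mean(big$features[big$labels == cl, f])
  expect_gt(mn("ASTV", "P"), mn("ASTV", "S"))
  expect_gt(mn("ASTV", "S"), mn("ASTV", "N"))
  expect_lt(mn("AC", "P"), mn("AC", "N"))
  expect_lt(mn("Mean", "P"), mn("Mean", "N"))
  expect_gt(mn("DP", "P"), mn("DP", "N"))
  # non-driver noise is class-independent (means near 0 for all classes)
  expect_true(all(abs(c(mn("LB", "N"), mn("LB", "P"))) < 0.5))

  expect_error(synthetic_spec(M = 2, feature_names = c("ASTV", "AC"),
                              drivers = list(ASTV = c(0, 1, 2), AC = c(0, -1, -1),
                                             DP = c(0, 0, 1))),
               class = "ctg_config_error")
  expect_error(synthetic_spec(n_per_class = c(3, 0)), class = "ctg_config_error")
})
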