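test_that("kernel weights match direct substitution and are symmetric", {
  expect_equal(shap_kernel_weight(3, 1), 1 / 3)
  expect_equal(shap_kernel_weight(4, 2), 0.125)
  for (M in 2:12) {
    s <- seq_len(M - 1)
    w <- shap_kernel_weight(M, s)
    expect_true(all(w > 0 & is.finite(w)))
    expect_equal(w, rev(shap_kernel_weight(M, M - s)), tolerance = 1e-14)
  }
  expect_error(shap_kernel_weight(5, 0), class = "ctg_input_error")
  expect_error(shap_kernel_weight(5, 5), class = "ctg_input_error")
})

test_that("exact enumeration yields all interior coalitions with the analytic weight sum", {
  sys3 <- build_coalition_system(3, shap_config())
  expect_identical(nrow(sys3$masks), 6L)
  expect_identical(sort(rowSums(sys3$masks)), c(1, 1, 1, 2, 2, 2))
  expect_identical(sys3$mode, "exact")

  # closed-form total: sum over s of choose(M,s) * pi(M,s)
  sys5 <- build_coalition_system(5, shap_config())
  s <- 1:4
  analytic <- sum(choose(5, s) * (5 - 1) / (choose(5, s) * s * (5 - s)))
  expect_equal(sum(sys5$weights), analytic, tolerance = 1e-12)
})

test_that("sampling mode pairs every mask with its complement, deterministically", {
  cfg <- shap_config(enum_limit = 4, sample_budget = 256, seed = 9)
  sys <- build_coalition_system(10, cfg)
  expect_identical(sys$mode, "sampled")
  keys <- apply(sys$masks, 1, paste, collapse = "")
  comp <- apply(1L - sys$masks, 1, paste, collapse = "")
  expect_true(all(comp %in% keys))
  # complements carry equal accumulated multiplicity
  expect_equal(sys$weights[match(comp, keys)], sys$weights)

  sys2 <- build_coalition_system(10, cfg)
  expect_identical(sys, sys2)
})

test_that("masked prediction hybridizes the instance with the background", {
  f <- function(m) cbind(m[, 1] * 10 + m[, 2])
  bg <- rbind(c(1, 2), c(3, 4))
  x <- c(5, 7)
  expect_equal(masked_prediction(f, x, c(1, 1), bg, 1), 57)          # full
  expect_equal(masked_prediction(f, x, c(0, 0), bg, 1), mean(c(12, 34)))
  expect_equal(masked_prediction(f, x, c(1, 0), bg[1, , drop = FALSE], 1), 52)
  expect_error(masked_prediction(f, x, c(1, 0), bg[0, , drop = FALSE]),
               class = "ctg_config_error")
})

test_that("the constrained regression recovers closed forms and obeys axioms", {
  bg <- withr::with_seed(3, matrix(rnorm(40), 10, 4,
                                   dimnames = list(NULL, paste0("F", 1:4))))
  # constant model: all attributions vanish, base value is the constant
  fconst <- function(m) matrix(7.5, nrow(m), 1)
  e <- explain_instance(fconst, rnorm(4), bg)[[1]]
  expect_equal(unname(e$shap_values), rep(0, 4), tolerance = 1e-10)
  expect_equal(e$base_value, 7.5)

  # linear model, single background row: phi_i = w_i (x_i - r_i) exactly
  w <- c(2, -1, 0.5, 3)
  flin <- function(m) m %*% w + 1
  r <- bg[1, , drop = FALSE]
  x <- withr::with_seed(4, rnorm(4))
  e <- explain_instance(flin, x, r)[[1]]
  expect_equal(unname(e$shap_values), w * (x - as.numeric(r)), tolerance = 1e-10)

  # dummy axiom: an ignored feature gets zero attribution
  fdummy <- function(m) cbind(3 * m[, 2] - m[, 4])
  e <- explain_instance(fdummy, c(9, 1, -9, 2), bg)[[1]]
  expect_lt(abs(e$shap_values[["F1"]]), 1e-8)
  expect_lt(abs(e$shap_values[["F3"]]), 1e-8)

  # symmetry axiom: interchangeable features share credit equally
  bgs <- cbind(bg[, 1], bg[, 1], bg[, 3:4])
  colnames(bgs) <- paste0("F", 1:4)
  fsym <- function(m) cbind(m[, 1] + m[, 2])
  e <- explain_instance(fsym, c(2, 2, 0, 0), bgs)[[1]]
  expect_equal(e$shap_values[["F1"]], e$shap_values[["F2"]], tolerance = 1e-6)

  expect_error(solve_shap_regression(matrix(0, 0, 3), numeric(0), numeric(0), 0, 1),
               class = "ctg_input_error")
})

test_that("per-class explanations satisfy local accuracy and sum to zero across classes", {
  fx <- shap_test_model(M = 6, seed = 21)
  bg <- shap_background(fx$dataset$features, 8, seed = 22)
  x <- fx$dataset$features[11, ]
  ex <- explain_instance(fx$f, x, bg, class_names = fx$dataset$class_names)
  for (e in ex) {
    expect_lt(abs(e$base_value + sum(e$shap_values) - e$fx), 1e-6)
  }
  cross_class <- ex[[1]]$shap_values + ex[[2]]$shap_values
  expect_true(all(abs(cross_class) < 1e-6))
})

test_that("the brute-force oracle matches hand enumeration and additive closed forms", {
  # additive model: phi_i = w_i (x_i - mean background_i)
  w <- c(1.5, -2)
  f <- function(m) m %*% w
  bg <- withr::with_seed(5, matrix(rnorm(12), 6, 2))
  x <- c(1, 2)
  phi <- exact_shapley_oracle(f, x, bg)
  expect_equal(unname(phi), w * (x - colMeans(bg)), tolerance = 1e-10)

  # M=2 interaction model, single reference: manual four-term computation
  fprod <- function(m) cbind(m[, 1] * m[, 2])
  r <- matrix(c(1, 1), 1, 2)
  x <- c(3, 5)
  v <- c(`00` = 1, `10` = 3 * 1, `01` = 1 * 5, `11` = 15)
  phi1_hand <- 0.5 * (v["10"] - v["00"]) + 0.5 * (v["11"] - v["01"])
  phi2_hand <- 0.5 * (v["01"] - v["00"]) + 0.5 * (v["11"] - v["10"])
  phi <- exact_shapley_oracle(fprod, x, r)
  expect_equal(unname(phi), unname(c(phi1_hand, phi2_hand)), tolerance = 1e-12)

  # efficiency axiom
  expect_lt(abs(sum(phi) - (fprod(matrix(x, 1)) - fprod(r))), 1e-10)
  expect_error(exact_shapley_oracle(f, rnorm(11), matrix(0, 2, 11)),
               class = "ctg_input_error")
})

test_that("sampled estimates converge to the exact solution as the budget grows", {
  fx <- shap_test_model(M = 8, seed = 31)
  bg <- shap_background(fx$dataset$features, 6, seed = 32)
  idx <- withr::with_seed(33, sample.int(nrow(fx$dataset$features), 5))
  exact_cfg <- shap_config(enum_limit = 8)
  errs <- vapply(c(256, 1024, 4096), function(budget) {
    cfg <- shap_config(enum_limit = 4, sample_budget = budget, seed = 34)
    devs <- vapply(idx, function(i) {
      x <- fx$dataset$features[i, ]
      est <- explain_instance(fx$f, x, bg, cfg)[[2]]
      ref <- explain_instance(fx$f, x, bg, exact_cfg)[[2]]
      max(abs(est$shap_values - ref$shap_values))
    }, 0)
    stats::median(devs)
  }, 0)
  expect_true(all(diff(errs) < 0))
  # local accuracy also holds in sampling mode
  cfg <- shap_config(enum_limit = 4, sample_budget = 256, seed = 35)
  e <- explain_instance(fx$f, fx$dataset$features[idx[1], ], bg, cfg)[[1]]
  expect_lt(abs(e$base_value + sum(e$shap_values) - e$fx), 1e-3)
})
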