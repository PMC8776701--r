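test_that("z-scoring uses training-only population moments", {
  tr <- cbind(a = c(1, 2, 3), b = c(10, 20, 40))
  te <- cbind(a = c(2, 5), b = c(20, 0))
  z <- zscore_fit_apply(tr, te)
  # population SD of (1,2,3) is sqrt(2/3): standardized -1.2247, 0, 1.2247
  expect_equal(unname(z$train[, "a"]), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(unname(z$train[, "a"])[2], 0)
  # test value equal to the training mean maps to 0
  expect_equal(unname(z$test[1, "a"]), 0)
  # training columns have mean 0, population SD 1
  expect_equal(unname(colMeans(z$train)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(z$train^2))), c(1, 1), tolerance = 1e-12)
  # idempotence on already-standardized input
  z2 <- zscore_fit_apply(z$train)
  expect_equal(z2$train, z$train, tolerance = 1e-12)
})

test_that("constant training features are dropped from both partitions", {
  tr <- cbind(a = c(1, 2, 3), flat = c(7, 7, 7))
  te <- cbind(a = c(1, 2), flat = c(7, 9))
  expect_warning(z <- zscore_fit_apply(tr, te), "flat")
  expect_equal(colnames(z$train), "a")
  expect_equal(colnames(z$test), "a")
  expect_equal(z$scaler_params$dropped, "flat")
})

test_that("scaler parameters do not depend on the test partition", {
  set.seed(2)
  tr <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  te <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, letters[1:4]))
  z1 <- zscore_fit_apply(tr, te)
  z2 <- zscore_fit_apply(tr, te[sample(5), ])
  expect_identical(z1$scaler_params, z2$scaler_params)
})

test_that("stratified splits follow the rounding rule and are deterministic", {
  set.seed(3)
  ft <- feature_table(data.frame(x = rnorm(10)), c(rep(1, 4), rep(0, 6)))
  sch <- split_scheme(train_fraction = 0.7, seed = 5)
  sp <- stratified_split(ft, sch, 1)
  # round(0.7 * 4) = 3 positives, round(0.7 * 6) = 4 negatives in training
  expect_equal(sum(sp$train$label), 3)
  expect_equal(sum(sp$train$label == 0), 4)
  expect_equal(sum(sp$test$label), 1)
  expect_equal(sum(sp$test$label == 0), 2)
  # determinism in (seed, repeat)
  sp2 <- stratified_split(ft, sch, 1)
  expect_identical(sp$train_idx, sp2$train_idx)
  sp3 <- stratified_split(ft, sch, 2)
  expect_false(identical(sp$train_idx, sp3$train_idx))
})

test_that("degenerate split requests are rejected", {
  expect_error(split_scheme(train_fraction = 1), "strictly")
  ft <- feature_table(data.frame(x = rnorm(6)), c(1, 1, 0, 0, 0, 0))
  # 0.9 * 2 positives rounds to 2: the test partition would lose the class
  expect_error(stratified_split(ft, split_scheme(train_fraction = 0.9), 1),
               "empty")
})

test_that("AUC matches pair enumeration, limits and invariances", {
  # 4 positive-negative pairs: 3 wins, 1 loss -> 0.75
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  # invariance under strictly increasing transforms
  set.seed(8)
  s <- rnorm(30); y <- rbinom(30, 1, 0.4); y[1] <- 1; y[2] <- 0
  expect_equal(auc(s, y), auc(exp(s) + 3, y))
  expect_error(auc(s, rep(1, 30)), "both classes")
})

test_that("the SMO-fitted SVM separates separable data and respects the box", {
  set.seed(21)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(rnorm(n, 3 * y), rnorm(n, -3 * y))
  fit <- svm_rbf(x, y, C = 10, gamma = 0.5)
  expect_equal(auc(predict(fit, x), y), 1)
  expect_true(all(predict(fit, x, type = "class") %in% c(0, 1)))
})

test_that("Bayesian tuning finds near-separating hyperparameters on separable data", {
  set.seed(22)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(rnorm(n, 3 * y), rnorm(n, 2 * y))
  tu <- tune_svm(x, y, inner_folds = 5, seed = 9)
  expect_gte(tu$cv_auc, 0.95)
  expect_true(tu$C >= 1e-3 && tu$C <= 1e3)
  expect_true(tu$gamma >= 1e-4 && tu$gamma <= 10)
  expect_equal(nrow(tu$trace), 30)
})

test_that("tuning with budget 1 returns the single evaluated point", {
  set.seed(23)
  n <- 24
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(2 * n), n, 2)
  tu <- tune_svm(x, y, inner_folds = 3, control = tune_control(budget = 1), seed = 4)
  expect_equal(nrow(tu$trace), 1)
  expect_equal(tu$C, tu$trace$C[1])
})

test_that("tuned inner-CV AUC stays in the null band under label permutation", {
  set.seed(24)
  n <- 40
  x <- matrix(rnorm(3 * n), n, 3)
  aucs <- replicate(10, {
    y <- sample(rep(c(0, 1), each = n / 2))
    tune_svm(x, y, inner_folds = 5, control = tune_control(budget = 10),
             seed = sample.int(1e6, 1))$cv_auc
  })
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.7)
})

test_that("tuning is deterministic given its seed", {
  set.seed(25)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(2 * n), n, 2)
  t1 <- tune_svm(x, y, inner_folds = 3, control = tune_control(budget = 12), seed = 77)
  t2 <- tune_svm(x, y, inner_folds = 3, control = tune_control(budget = 12), seed = 77)
  expect_identical(t1$trace, t2$trace)
})

test_that("paired Wilcoxon comparison matches exact enumeration", {
  # 5 uniformly positive differences: two-sided exact p = 2/2^5 = 0.0625
  a <- c(0.71, 0.66, 0.74, 0.69, 0.80)
  b <- a - c(0.02, 0.05, 0.01, 0.04, 0.03)
  expect_equal(compare_feature_sets(a, b), 0.0625)
  # symmetric in sign
  expect_equal(compare_feature_sets(b, a), 0.0625)
  # no signal: identical inputs
  expect_warning(p1 <- compare_feature_sets(a, a), "zero")
  expect_equal(p1, 1)
})

test_that("Mann-Whitney screen matches exact enumeration", {
  ft <- feature_table(data.frame(f = c(1, 2, 3, 4, 5, 6)),
                      c(1, 1, 1, 0, 0, 0))
  # U = 0 for fully separated groups of 3: exact two-sided p = 2/C(6,3) = 0.1
  expect_equal(unname(univariate_screen(ft)["f"]), 0.1)
  # label swap leaves p unchanged
  ft2 <- feature_table(ft$features, 1 - ft$label)
  expect_equal(univariate_screen(ft2), univariate_screen(ft))
  # identical groups: p near 1
  ft3 <- feature_table(data.frame(f = rep(c(1, 2, 3), 2)),
                       c(1, 1, 1, 0, 0, 0))
  expect_gt(unname(univariate_screen(ft3)["f"]), 0.9)
})

test_that("Spearman correlations match rank arithmetic", {
  df <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
  m <- correlation_matrix(df)
  # sum of squared rank differences is 4: rho = 1 - 6*4/(125 - 5) = 0.8
  expect_equal(m["x", "y"], 0.8)
  df2 <- data.frame(a = 1:6, up = (1:6)^3, down = -(1:6))
  m2 <- correlation_matrix(df2)
  expect_equal(m2["a", "up"], 1)
  expect_equal(m2["a", "down"], -1)
  expect_true(isSymmetric(m2) && all(diag(m2) == 1))
  expect_warning(m3 <- correlation_matrix(data.frame(a = 1:5, k = rep(2, 5))),
                 "constant")
  expect_true(is.na(m3["a", "k"]))
})

test_that("experiment keeps the paired design: identical splits across sets", {
  co <- small_cohort()
  ex <- cached("exp_small",
               run_experiment(co$table,
                              scheme = split_scheme(n_repeats = 4, inner_folds = 3,
                                                    seed = 11),
                              control = tune_control(budget = 8)))
  expect_equal(nrow(ex$runs), 4 * 4)
  expect_true(all(ex$runs$test_auc >= 0 & ex$runs$test_auc <= 1))
  expect_true(all(ex$runs$C >= 1e-3 & ex$runs$C <= 1e3))
  expect_true(all(ex$runs$gamma >= 1e-4 & ex$runs$gamma <= 10))
  # splits depend only on (scheme seed, repeat): re-derive and compare
  sch <- split_scheme(n_repeats = 4, inner_folds = 3, seed = 11)
  s1 <- stratified_split(co$table, sch, 2)
  s2 <- stratified_split(co$table, sch, 2)
  expect_identical(s1$train_idx, s2$train_idx)
  # summary statistics are recomputable from the stored runs
  s <- summary(ex)
  te <- ex$runs$test_auc[ex$runs$set == "clinical_dvh_dfh"]
  expect_equal(s$table$median_test_auc[s$table$set == "clinical_dvh_dfh"],
               median(te))
})

test_that("noiseless monotone labels give perfect test AUC for sets holding the column", {
  co <- small_cohort()
  y_perfect <- as.integer(co$table$features$fV20 >
                            median(co$table$features$fV20))
  ft <- feature_table(co$table$features, y_perfect)
  ex <- run_experiment(ft, feature_sets = list(dfh_only = c("fMLD", "fV5", "fV10",
                                                            "fV20", "fV30", "fV40",
                                                            "fV50")),
                       scheme = split_scheme(n_repeats = 3, inner_folds = 3, seed = 13),
                       control = tune_control(budget = 10))
  expect_true(all(ex$runs$test_auc > 0.9))
})

test_that("DFH-loaded labels favour feature sets that include DFH", {
  ex <- signal_experiment()
  s <- summary(ex)$table
  med <- function(set) s$median_test_auc[s$set == set]
  expect_gt(med("clinical_dfh"), med("clinical"))
  expect_gt(med("clinical_dvh_dfh"), med("clinical"))
})
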