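#' Feature table: the modeling substrate
#'
#' Patients by named features plus a binary radiation-pneumonitis label
#' (grade >= 2). No missing values are allowed and both classes must be
#' present.
#'
#' @param features data.frame or matrix of numeric features with names.
#' @param label binary vector in \{0, 1\}.
#' @param patient_id optional character ids (defaults to row numbers).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features, label, patient_id = NULL) {
  features <- as.data.frame(features)
  if (anyNA(features)) stop("feature table contains missing values")
  if (!all(vapply(features, is.numeric, TRUE))) stop("all features must be numeric")
  if (nrow(features) != length(label)) stop("label length != patient count")
  if (!all(label %in% c(0, 1)) || length(unique(label)) < 2)
    stop("label must contain both classes, coded 0/1")
  if (is.null(patient_id)) patient_id <- sprintf("P%03d", seq_len(nrow(features)))
  structure(list(patient_id = as.character(patient_id), features = features,
                 label = as.integer(label)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d patients x %d features, %d/%d RP-positive (%.1f%%)\n",
              nrow(x$features), ncol(x$features), sum(x$label),
              length(x$label), 100 * mean(x$label)))
  invisible(x)
}

ft_subset <- function(ft, idx)
  feature_table(ft$features[idx, , drop = FALSE], ft$label[idx], ft$patient_id[idx])

#' The four nested candidate feature sets
#'
#' (i) patient clinical features; (ii) clinical + DVH; (iii) clinical + DFH;
#' (iv) clinical + DVH + DFH.
#'
#' @return named list of character vectors of feature names.
#' @export
default_feature_sets <- function() {
  clinical <- c("age", "brinkman_index", "gitv_pos_ul", "gitv_pos_ap",
                "gitv_pos_lr", "gitv_volume_cc")
  dvh <- c("MLD", paste0("V", dvh_thresholds_Gy))
  dfh <- c("fMLD", paste0("fV", dvh_thresholds_Gy))
  list(clinical = clinical,
       clinical_dvh = c(clinical, dvh),
       clinical_dfh = c(clinical, dfh),
       clinical_dvh_dfh = c(clinical, dvh, dfh))
}

#' Split scheme for repeated stratified evaluation
#'
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.7, a 70/30 split).
#' @param n_repeats number of independent repeats (default 50 models).
#' @param inner_folds stratified folds of the inner hyperparameter CV.
#' @param seed master seed; per-repeat split seeds and optimizer seeds are
#'   derived from it deterministically.
#' @return list of class `split_scheme`.
#' @export
split_scheme <- function(train_fraction = 0.7, n_repeats = 50L,
                         inner_folds = 5L, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie strictly in (0, 1): both partitions must be nonempty")
  structure(list(train_fraction = train_fraction,
                 n_repeats = as.integer(n_repeats),
                 inner_folds = as.integer(inner_folds),
                 seed = as.integer(seed)),
            class = "split_scheme")
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Samples each class without replacement, assigning
#' `round(train_fraction * class size)` members to training (half-up
#' rounding), so the class balance is preserved in both partitions.
#' Deterministic given `(scheme$seed, repeat_idx)`.
#'
#' @param ft a [feature_table()].
#' @param scheme a [split_scheme()].
#' @param repeat_idx 1-based repeat index.
#' @return list with `train` and `test` feature tables and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
stratified_split <- function(ft, scheme, repeat_idx) {
  if (!inherits(ft, "feature_table")) stop("'ft' must be a feature_table")
  y <- ft$label
  if (min(table(y)) < 2) stop("both classes need >= 2 members to split")
  set.seed(derive_seed(scheme$seed, repeat_idx, salt = 101))
  train_idx <- integer(0)
  for (cl in c(0, 1)) {
    idx <- which(y == cl)
    n_tr <- round_half_up(scheme$train_fraction * length(idx))
    if (n_tr < 1 || n_tr >= length(idx))
      stop(sprintf("class %d would leave an empty partition (train %d of %d)",
                   cl, n_tr, length(idx)))
    train_idx <- c(train_idx, sample(idx)[seq_len(n_tr)])
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = ft_subset(ft, train_idx), test = ft_subset(ft, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Z-score standardization fitted on the training partition
#'
#' Estimates per-feature mean and population standard deviation
#' (denominator N) on the training partition only and applies them to both
#' partitions, so no information leaks from test to train. Features constant
#' in training are dropped from both partitions with a warning.
#'
#' @param train,test numeric matrices or data.frames with common columns.
#' @return list with standardized `train`, `test` matrices and
#'   `scaler_params` (`center`, `scale`, `dropped`).
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- sqrt(colMeans(sweep(train, 2, ctr)^2))
  dropped <- colnames(train)[scl < 1e-12]
  if (length(dropped)) {
    warning(sprintf("dropping constant training feature(s): %s",
                    paste(dropped, collapse = ", ")))
    keep <- scl >= 1e-12
    train <- train[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  std <- function(m) sweep(sweep(as.matrix(m)[, names(ctr), drop = FALSE],
                                 2, ctr), 2, scl, "/")
  list(train = std(train),
       test = if (is.null(test)) NULL else std(test),
       scaler_params = list(center = ctr, scale = scl, dropped = dropped))
}

#' Area under the ROC curve
#'
#' Rank-based AUC: the probability that a randomly chosen positive case
#' outscores a randomly chosen negative one, ties counting one half.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels in \{0, 1\}; both classes required.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2)
    stop("labels must contain both classes")
  r <- rank(scores, ties.method = "average")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the repeated-split model-development experiment
#'
#' For each of `scheme$n_repeats` stratified 70/30 splits and each candidate
#' feature set: standardize on training, tune `(C, gamma)` by Bayesian
#' optimization through stratified inner CV, fit the RBF-SVM on the full
#' training partition, and record the decision-score AUC on both partitions.
#' Within one repeat all feature sets see the identical split (paired
#' design), so set comparisons are paired by repeat.
#'
#' @param ft a [feature_table()].
#' @param feature_sets named list of feature-name vectors (default the four
#'   nested sets of [default_feature_sets()]).
#' @param scheme a [split_scheme()].
#' @param control a [tune_control()].
#' @return object of class `rp_experiment`: `runs` (one row per repeat and
#'   set: `repeat_idx, set, C, gamma, train_auc, test_auc`), plus the scheme
#'   and control used.
#' @export
run_experiment <- function(ft, feature_sets = default_feature_sets(),
                           scheme = split_scheme(), control = tune_control()) {
  if (!inherits(ft, "feature_table")) stop("'ft' must be a feature_table")
  missing_cols <- setdiff(unique(unlist(feature_sets)), names(ft$features))
  if (length(missing_cols))
    stop(sprintf("feature sets reference unknown columns: %s",
                 paste(missing_cols, collapse = ", ")))
  runs <- vector("list", scheme$n_repeats * length(feature_sets))
  k <- 0L
  for (r in seq_len(scheme$n_repeats)) {
    sp <- tryCatch(stratified_split(ft, scheme, r),
                   error = function(e) stop(sprintf("repeat %d: %s", r, conditionMessage(e))))
    for (si in seq_along(feature_sets)) {
      set_name <- names(feature_sets)[si]
      cols <- feature_sets[[si]]
      z <- suppressWarnings(zscore_fit_apply(sp$train$features[, cols, drop = FALSE],
                                             sp$test$features[, cols, drop = FALSE]))
      tuned <- tune_svm(z$train, sp$train$label, scheme$inner_folds, control,
                        seed = derive_seed(scheme$seed, r, salt = 1000 + si))
      fit <- svm_rbf(z$train, sp$train$label, C = tuned$C, gamma = tuned$gamma)
      k <- k + 1L
      runs[[k]] <- data.frame(
        repeat_idx = r, set = set_name, C = tuned$C, gamma = tuned$gamma,
        inner_cv_auc = tuned$cv_auc,
        train_auc = auc(predict(fit, z$train), sp$train$label),
        test_auc = auc(predict(fit, z$test), sp$test$label))
    }
  }
  structure(list(runs = do.call(rbind, runs), feature_sets = feature_sets,
                 scheme = scheme, control = control),
            class = "rp_experiment")
}

experiment_set_aucs <- function(x, set, partition = "test_auc") {
  r <- x$runs[x$runs$set == set, ]
  r[order(r$repeat_idx), partition]
}

#' Paired comparison of two feature sets
#'
#' Two-sided paired Wilcoxon signed-rank test on per-repeat test AUCs.
#' Zero differences are dropped; the exact distribution is used for up to 25
#' informative pairs, the tie-corrected normal approximation beyond that.
#' When every difference is zero the test is vacuous: p = 1 with a warning.
#'
#' @param a,b numeric vectors of per-repeat AUCs paired by repeat, or
#'   `ModelRun` data.frames with a `test_auc` column.
#' @return two-sided p-value.
#' @export
compare_feature_sets <- function(a, b) {
  if (is.data.frame(a)) a <- a$test_auc
  if (is.data.frame(b)) b <- b$test_auc
  if (length(a) != length(b)) stop("inputs must be paired (equal length)")
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(a, b, paired = TRUE, exact = nz <= 25, correct = TRUE)$p.value)
}

#' Per-feature univariate screen
#'
#' Two-sided Mann-Whitney U test of each feature between RP-positive and
#' RP-negative patients (exact for combined n <= 20 without ties, normal
#' approximation with tie correction otherwise).
#'
#' @param ft a [feature_table()].
#' @return named vector of p-values.
#' @export
univariate_screen <- function(ft) {
  if (!inherits(ft, "feature_table")) stop("'ft' must be a feature_table")
  y <- ft$label
  n <- length(y)
  vapply(ft$features, function(x)
    suppressWarnings(wilcox.test(x[y == 1], x[y == 0],
                                 exact = n <= 20)$p.value),
    0)
}

#' Spearman correlation matrix of selected features
#'
#' @param ft a [feature_table()] (or data.frame) with >= 3 patients.
#' @param columns feature names (default all).
#' @return symmetric correlation matrix with unit diagonal; entries for
#'   constant columns are `NA` and flagged with a warning.
#' @export
correlation_matrix <- function(ft, columns = NULL) {
  df <- if (inherits(ft, "feature_table")) ft$features else as.data.frame(ft)
  if (nrow(df) < 3) stop("need >= 3 patients for rank correlation")
  if (!is.null(columns)) df <- df[, columns, drop = FALSE]
  const <- names(df)[vapply(df, function(x) length(unique(x)) == 1, TRUE)]
  m <- suppressWarnings(cor(as.matrix(df), method = "spearman"))
  if (length(const)) {
    warning(sprintf("constant column(s) give undefined correlations: %s",
                    paste(const, collapse = ", ")))
    m[const, ] <- NA; m[, const] <- NA
  }
  diag(m) <- 1
  m
}

#' @export
print.rp_experiment <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<rp_experiment> %d repeats x %d feature sets (%.0f/%.0f split)\n",
              x$scheme$n_repeats, length(x$feature_sets),
              100 * x$scheme$train_fraction, 100 * (1 - x$scheme$train_fraction)))
  print(s$table[, c("set", "median_test_auc", "iqr_test_auc", "median_train_auc")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Summarize an experiment
#'
#' Per feature set: median and mean AUC on both partitions, the IQR and the
#' quartile deviation (Q3 - Q1)/2 of the test AUCs, and two 95% intervals
#' across the repeats (percentile and normal-theory, both reported because
#' the construction across repeated splits is a convention, not a theorem).
#' Pairwise paired Wilcoxon p-values on test AUCs are included.
#'
#' @param object an `rp_experiment`.
#' @param ... unused.
#' @return list of class `summary.rp_experiment` with elements `table` and
#'   `pairwise_p`.
#' @export
summary.rp_experiment <- function(object, ...) {
  sets <- names(object$feature_sets)
  rows <- lapply(sets, function(s) {
    te <- experiment_set_aucs(object, s, "test_auc")
    tr <- experiment_set_aucs(object, s, "train_auc")
    q <- quantile(te, c(0.25, 0.75), names = FALSE)
    se <- sd(te) / sqrt(length(te))
    data.frame(set = s,
               median_test_auc = median(te), mean_test_auc = mean(te),
               iqr_test_auc = q[2] - q[1], quartile_dev_test_auc = (q[2] - q[1]) / 2,
               ci95_lo_pctl = quantile(te, 0.025, names = FALSE),
               ci95_hi_pctl = quantile(te, 0.975, names = FALSE),
               ci95_lo_norm = mean(te) - qnorm(0.975) * se,
               ci95_hi_norm = mean(te) + qnorm(0.975) * se,
               median_train_auc = median(tr), mean_train_auc = mean(tr))
  })
  pw <- matrix(NA_real_, length(sets), length(sets), dimnames = list(sets, sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) if (i != j)
    pw[i, j] <- suppressWarnings(compare_feature_sets(
      experiment_set_aucs(object, sets[i]), experiment_set_aucs(object, sets[j])))
  structure(list(table = do.call(rbind, rows), pairwise_p = pw),
            class = "summary.rp_experiment")
}

#' @export
print.summary.rp_experiment <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 3)
  cat("\nPaired Wilcoxon p-values (test AUC):\n")
  print(signif(x$pairwise_p, 3))
  invisible(x)
}

#' @rdname run_experiment
#' @param x an `rp_experiment`.
#' @param partition `"test_auc"` or `"train_auc"`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.rp_experiment <- function(x, partition = c("test_auc", "train_auc"), ...) {
  partition <- match.arg(partition)
  sets <- names(x$feature_sets)
  vals <- lapply(sets, experiment_set_aucs, x = x, partition = partition)
  names(vals) <- sets
  graphics::boxplot(vals, ylab = sub("_", " ", partition),
                    main = sprintf("AUC over %d repeats", x$scheme$n_repeats), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}
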