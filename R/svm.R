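sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  pmax(outer(an, bn, "+") - 2 * tcrossprod(a, b), 0)
}

#' RBF-kernel support vector classifier
#'
#' C-SVC with a radial-basis-function kernel
#' `K(x, x') = exp(-gamma ||x - x'||^2)`, fitted by sequential minimal
#' optimization on the dual. `C` is the misclassification penalty, `gamma`
#' the inverse squared kernel width. Features should be standardized first
#' (see [zscore_fit_apply()]).
#'
#' @param x numeric matrix (patients x features).
#' @param y binary labels in \{0, 1\}; both classes required.
#' @param C,gamma positive hyperparameters.
#' @param tol SMO stopping tolerance on the KKT violation.
#' @param max_iter iteration cap for the SMO solver.
#' @return object of class `svm_rbf`.
#' @export
svm_rbf <- function(x, y, C = 1, gamma = 1 / ncol(x), tol = 1e-3,
                    max_iter = 100000L) {
  x <- as.matrix(x)
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop("'y' must contain both classes, coded 0/1")
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  K <- exp(-gamma * sqdist(x, x))
  ypm <- 2 * y - 1
  fit <- svm_train_cpp(K, ypm, C, tol, as.integer(max_iter))
  structure(list(x = x, coef = fit$alpha * ypm, b = fit$b,
                 C = C, gamma = gamma, iter = fit$iter,
                 n_sv = sum(fit$alpha > 1e-8)),
            class = "svm_rbf")
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat(sprintf("<svm_rbf> C = %.4g, gamma = %.4g, %d support vectors of %d samples\n",
              x$C, x$gamma, x$n_sv, nrow(x$x)))
  invisible(x)
}

#' @rdname svm_rbf
#' @param object fitted `svm_rbf`.
#' @param newdata matrix of cases to score.
#' @param type `"decision"` for signed margins (used for AUC) or `"class"`
#'   for 0/1 predictions.
#' @param ... unused.
#' @export
predict.svm_rbf <- function(object, newdata, type = c("decision", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  dec <- drop(exp(-object$gamma * sqdist(newdata, object$x)) %*% object$coef) +
    object$b
  if (type == "decision") dec else as.integer(dec > 0)
}

# stratified fold assignment; every held-out fold contains both classes
# provided each class has at least `k` members
stratified_folds <- function(y, k, seed) {
  counts <- table(y)
  if (min(counts) < k)
    stop(sprintf("cannot build %d stratified folds: smallest class has %d members",
                 k, min(counts)))
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tuner search-space and budget control
#'
#' The log-uniform search box and evaluation budget of the Bayesian
#' hyperparameter optimization: `C` in \[1e-3, 1e3\], `gamma` in
#' \[1e-4, 10\], 30 objective evaluations of which the first `n_init` form a
#' seeded Latin-hypercube design.
#'
#' @param budget total objective evaluations.
#' @param n_init initial space-filling evaluations before the GP is used.
#' @param C_range,gamma_range search box limits.
#' @param n_candidates random candidates scored by expected improvement per
#'   iteration.
#' @param gp_lengthscale,gp_noise squared-exponential GP surrogate
#'   hyperparameters on the unit square.
#' @return list of class `tune_control`.
#' @export
tune_control <- function(budget = 30L, n_init = 8L,
                         C_range = c(1e-3, 1e3), gamma_range = c(1e-4, 10),
                         n_candidates = 256L,
                         gp_lengthscale = 0.2, gp_noise = 1e-3) {
  if (budget < 1) stop("'budget' must be >= 1")
  structure(list(budget = as.integer(budget), n_init = as.integer(n_init),
                 C_range = C_range, gamma_range = gamma_range,
                 n_candidates = as.integer(n_candidates),
                 gp_lengthscale = gp_lengthscale, gp_noise = gp_noise),
            class = "tune_control")
}

# expected-improvement proposal from a squared-exponential GP surrogate
gp_ei_propose <- function(U, yv, cand, ls, noise) {
  ymean <- mean(yv)
  ysd <- stats::sd(yv)
  if (!is.finite(ysd) || ysd < 1e-8) ysd <- 1
  yz <- (yv - ymean) / ysd
  m <- nrow(U)
  Kxx <- exp(-0.5 * sqdist(U, U) / ls^2) + diag(noise, m)
  L <- chol(Kxx)
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  Ks <- exp(-0.5 * sqdist(cand, U) / ls^2)
  mu <- drop(Ks %*% alpha)
  v <- forwardsolve(t(L), t(Ks))
  s <- sqrt(pmax(1 - colSums(v^2), 1e-12))
  z <- (mu - max(yz)) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  cand[which.max(ei), , drop = FALSE]
}

#' Bayesian optimization of the SVM hyperparameters
#'
#' Maximizes the mean inner-cross-validated AUC of the RBF-SVM over a
#' log-uniform box in `(C, gamma)` using a Gaussian-process surrogate with
#' expected-improvement acquisition: a seeded Latin-hypercube start, then
#' one objective evaluation per iteration at the best candidate. The
#' objective for one point is the mean AUC over `inner_folds` stratified
#' folds of the training partition.
#'
#' @param x standardized training feature matrix.
#' @param y binary training labels.
#' @param inner_folds number of stratified inner CV folds (default 5).
#' @param control a [tune_control()].
#' @param seed integer seed for the fold assignment, the initial design and
#'   the candidate draws.
#' @return list with `C`, `gamma`, `cv_auc` (best mean inner-CV AUC) and
#'   `trace` (one row per evaluation).
#' @export
tune_svm <- function(x, y, inner_folds = 5L, control = tune_control(),
                     seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2) stop("training labels contain one class")
  fold <- stratified_folds(y, inner_folds, derive_seed(seed, 1, salt = 31))
  D2 <- sqdist(x, x)
  lo <- log10(c(control$C_range[1], control$gamma_range[1]))
  hi <- log10(c(control$C_range[2], control$gamma_range[2]))
  to_params <- function(u) 10^(lo + u * (hi - lo))
  objective <- function(u) {
    p <- to_params(u)
    cv_auc_cpp(D2, as.integer(y), as.integer(fold), p[1], p[2])
  }
  set.seed(derive_seed(seed, 2, salt = 47))
  n_init <- min(control$n_init, control$budget)
  U <- cbind((sample(n_init) - runif(n_init)) / n_init,
             (sample(n_init) - runif(n_init)) / n_init)
  vals <- apply(U, 1, objective)
  while (nrow(U) < control$budget) {
    cand <- matrix(runif(2 * control$n_candidates), ncol = 2)
    u_new <- gp_ei_propose(U, vals, cand, control$gp_lengthscale, control$gp_noise)
    U <- rbind(U, u_new)
    vals <- c(vals, objective(drop(u_new)))
  }
  params <- t(apply(U, 1, to_params))
  best <- which.max(vals)
  list(C = params[best, 1], gamma = params[best, 2], cv_auc = vals[best],
       trace = data.frame(iter = seq_along(vals), C = params[, 1],
                          gamma = params[, 2], cv_auc = vals))
}
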