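#' Fit a two-class quadratic discriminant model on PC scores
#'
#' Class means are the sample means of the first `k` components and class
#' covariances the unbiased sample covariances. When a covariance is
#' ill-conditioned (condition number above 1e10, as happens for small or
#' near-degenerate training classes) a ridge of `1e-6 * trace / k` (floored
#' at 1e-8) is added to its diagonal until it is positive definite. Priors
#' default to the training class proportions; an equal-priors mode is
#' available because habitat-unbalanced training sets are common.
#'
#' @param scores numeric matrix (samples x >= k components).
#' @param labels factor/character vector with classes `"marine"` and
#'   `"freshwater"`.
#' @param k number of leading components used (1..4 typical).
#' @param priors_mode `"proportions"` or `"equal"`.
#' @return A `qda_model`: per-class means, covariances, Cholesky factors,
#'   log-determinants, priors, `k`.
#' @export
qda_fit <- function(scores, labels, k = 1,
                    priors_mode = c("proportions", "equal")) {
  priors_mode <- match.arg(priors_mode)
  scores <- as.matrix(scores)
  if (k > ncol(scores)) stop("k exceeds the number of components available")
  labels <- as.character(labels)
  classes <- c("marine", "freshwater")
  if (!all(labels %in% classes)) stop("labels must be marine/freshwater")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  x <- scores[, seq_len(k), drop = FALSE]
  # Class covariances are floored at a small fraction of the total
  # training-score variance (between-class scatter included). Without the
  # floor, a near-degenerate class's variance estimate is sampling noise,
  # and for points far from both centroids the posterior is then decided
  # by the arbitrary variance ratio instead of by distance. Classes whose
  # covariance is already on the problem scale are unaffected.
  floor_ridge <- 1e-2 * max(mean(diag(as.matrix(stats::cov(x)))), 0) + 1e-12
  fit_class <- function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    if (nrow(xi) < 2)
      stop("class ", cl, " has one sample; use a smaller k or more samples")
    mu <- colMeans(xi)
    S <- stats::cov(xi)
    S <- regularize_cov(S, floor_ridge)
    R <- chol(S)
    list(mu = mu, sigma = S, chol = R,
         logdet = 2 * sum(log(diag(R))), n = nrow(xi))
  }
  cl_fits <- lapply(classes, fit_class)
  names(cl_fits) <- classes
  priors <- if (priors_mode == "equal") c(0.5, 0.5)
  else vapply(cl_fits, `[[`, numeric(1), "n") / length(labels)
  names(priors) <- classes
  structure(list(classes = classes, fits = cl_fits, priors = priors, k = k,
                 priors_mode = priors_mode),
            class = "qda_model")
}

# ridge-regularize a covariance matrix: raise the smallest eigenvalue to
# `floor` when it falls below it, then ridge until well-conditioned
regularize_cov <- function(S, floor = 1e-8) {
  S <- (S + t(S)) / 2
  k <- nrow(S)
  min_ev <- function(S) min(eigen(S, symmetric = TRUE,
                                  only.values = TRUE)$values)
  cond_of <- function(S) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }
  me <- min_ev(S)
  if (me < floor) S <- S + diag(floor - me, k)
  ridge <- max(1e-6 * sum(diag(S)) / k, floor)
  guard <- 0L
  while (cond_of(S) > 1e10 && guard < 60L) {
    S <- S + diag(ridge, k)
    ridge <- ridge * 10
    guard <- guard + 1L
  }
  S
}

#' Probability of Freshwater Genotype from a QDA model
#'
#' `PFG = pi_F N(x; mu_F, Sigma_F) / sum_c pi_c N(x; mu_c, Sigma_c)`,
#' evaluated in log space.
#'
#' @param model a [qda_fit()] result.
#' @param x numeric vector of length `k`, or a matrix with `k` columns.
#' @return PFG in \[0, 1\] (vector for matrix input).
#' @export
qda_posterior <- function(model, x) {
  x <- if (is.null(dim(x))) matrix(x, ncol = model$k) else
    as.matrix(x)[, seq_len(model$k), drop = FALSE]
  if (any(!is.finite(x))) stop("non-finite input to qda_posterior")
  logd <- vapply(model$classes, function(cl) {
    f <- model$fits[[cl]]
    z <- backsolve(f$chol, t(x) - f$mu, transpose = TRUE)
    mah <- colSums(z^2)
    -0.5 * (model$k * log(2 * pi) + f$logdet + mah) +
      log(model$priors[[cl]])
  }, numeric(nrow(x)))
  logd <- matrix(logd, ncol = 2,
                 dimnames = list(NULL, model$classes))
  m <- pmax(logd[, 1], logd[, 2])
  pf <- exp(logd[, "freshwater"] - m) /
    (exp(logd[, "marine"] - m) + exp(logd[, "freshwater"] - m))
  unname(pf)
}

#' Leave-one-out cross-validated accuracy
#'
#' For each training sample the model is refit on the remaining `n - 1`
#' samples and the held-out sample classified at a posterior threshold of
#' 0.5 (PFG strictly above 0.5 is called freshwater). A fold whose refit is
#' impossible (a class collapses to one sample) counts as incorrect with a
#' warning.
#'
#' @inheritParams qda_fit
#' @return Fraction of correctly classified hold-outs.
#' @export
loo_cv_accuracy <- function(scores, labels, k = 1,
                            priors_mode = c("proportions", "equal")) {
  priors_mode <- match.arg(priors_mode)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 4) stop("need at least 4 samples for LOO-CV")
  correct <- logical(n)
  failed <- 0L
  for (i in seq_len(n)) {
    m <- tryCatch(qda_fit(scores[-i, , drop = FALSE], labels[-i], k,
                          priors_mode),
                  error = function(e) NULL)
    if (is.null(m)) { failed <- failed + 1L; next }
    pfg <- qda_posterior(m, scores[i, seq_len(k)])
    pred <- if (pfg > 0.5) "freshwater" else "marine"
    correct[i] <- pred == labels[i]
  }
  if (failed > 0)
    warning(failed, " LOO fold(s) could not be refit; counted incorrect")
  mean(correct)
}

#' Select the best QDA model over 1..k_max components
#'
#' Fits candidate models using the first 1, 2, ..., `k_max` components,
#' scores each by LOO-CV accuracy, and picks the highest accuracy (ties go
#' to the smallest `k`). The cluster is retained only when the chosen
#' accuracy is strictly above `accuracy_gate`. All candidate accuracies are
#' stored on the returned model.
#'
#' @inheritParams qda_fit
#' @param k_max largest number of components tried.
#' @param accuracy_gate retention threshold (strict).
#' @return A `qda_model` with elements `loo_accuracy`, `accuracies`
#'   (all candidates) and `retained`; `NULL` when no candidate is feasible.
#' @export
select_model <- function(scores, labels, k_max = 4, accuracy_gate = 0.75,
                         priors_mode = c("proportions", "equal")) {
  priors_mode <- match.arg(priors_mode)
  scores <- as.matrix(scores)
  ks <- seq_len(min(k_max, ncol(scores)))
  acc <- rep(NA_real_, length(ks))
  for (k in ks)
    acc[k] <- tryCatch(loo_cv_accuracy(scores, labels, k, priors_mode),
                       error = function(e) NA_real_)
  if (all(is.na(acc))) return(NULL)
  best_k <- which(acc == max(acc, na.rm = TRUE))[1]  # ties -> smallest k
  model <- qda_fit(scores, labels, best_k, priors_mode)
  model$loo_accuracy <- acc[best_k]
  model$accuracies <- stats::setNames(acc, paste0("k", ks))
  model$retained <- acc[best_k] > accuracy_gate
  model
}

#' @export
print.qda_model <- function(x, ...) {
  cat("QDA model: k =", x$k, " priors =",
      paste(sprintf("%s %.2f", x$classes, x$priors), collapse = ", "), "\n")
  if (!is.null(x$loo_accuracy))
    cat(sprintf("  LOO accuracy %.3f (%s)\n", x$loo_accuracy,
                if (isTRUE(x$retained)) "retained" else "not retained"))
  invisible(x)
}
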