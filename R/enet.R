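# Elastic-net regression solved by cyclic coordinate descent, with the
# penalized objective exactly as printed:
#
#   beta = argmin ( ||y - X beta||^2 + lambda2 ||beta||^2 + lambda1 ||beta||_1 )
#
# (no 1/2n factor). X is standardized column-wise (population SD) and y
# centered before solving; coefficients are reported back on the original
# feature scale. The mapping to glmnet's per-observation parameterization,
# lambda_glmnet = (lambda1/2 + lambda2)/n and alpha = lambda1 / (lambda1 +
# 2 lambda2), is used only by the test-suite oracle.

#' Construct a design matrix for penalized regression
#'
#' Centers and standardizes features (population SD); zero-variance columns
#' are dropped from the solve and reported, with zero coefficients restored
#' in the output ordering.
#'
#' @param X n x p numeric feature matrix (column names kept).
#' @param y Outcome vector, length n.
#' @return List of class \code{design_matrix}: standardized \code{Z},
#'   centered \code{yc}, standardization parameters and dropped columns.
#' @export
design_matrix <- function(X, y) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("design matrix must not contain NAs")
  if (nrow(X) == 0 || ncol(X) == 0) stop("empty design matrix")
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2, mu)^2))
  keep <- sdev > 0
  Z <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  Z <- sweep(Z, 2, sdev[keep], "/")
  yc <- y - mean(y)
  # Gram quantities cached once; every penalized fit reuses them
  structure(list(Z = Z, yc = yc, y_mean = mean(y),
                 center = mu, scale = sdev, keep = keep,
                 names = colnames(X),
                 G = crossprod(Z), cxy = drop(crossprod(Z, yc)),
                 yty = sum(yc^2)), class = "design_matrix")
}

#' Construct an elastic-net model object directly
#'
#' Builds a fitted-model container from known quantities, e.g. a published
#' coefficient listing. Features are on the standardized scale defined by
#' \code{center}/\code{scale}.
#'
#' @param intercept Model intercept (original outcome scale).
#' @param beta Named coefficient vector on the standardized feature scale.
#' @param lambda1,lambda2 Penalties used.
#' @param center,scale Standardization parameters per feature (defaults 0/1).
#' @return Object of class \code{elastic_net_model}.
#' @export
elastic_net_model <- function(intercept, beta, lambda1 = NA, lambda2 = NA,
                              center = NULL, scale = NULL) {
  p <- length(beta)
  if (is.null(center)) center <- rep(0, p)
  if (is.null(scale)) scale <- rep(1, p)
  if (is.null(names(beta))) names(beta) <- paste0("x", seq_len(p))
  beta_orig <- beta / scale
  structure(list(
    intercept = intercept - sum(beta_orig * center),
    beta = beta_orig,
    beta_std = beta, y_mean = intercept,
    center = center, scale = scale,
    lambda1 = lambda1, lambda2 = lambda2,
    k = sum(beta != 0), converged = TRUE, sweeps = 0L),
    class = "elastic_net_model")
}

#' Fit the elastic net at fixed penalties
#'
#' Cyclic coordinate descent with soft-threshold updates
#' \eqn{\beta_j \leftarrow S(x_j^T r_{(-j)}, \lambda_1/2) / (x_j^T x_j +
#' \lambda_2)}, converged when the largest coefficient change in a sweep
#' falls below \code{tol}. With \eqn{\lambda_1 \ge 2 \max_j |x_j^T y_c|} (on
#' the standardized scale) the solution is exactly zero and the intercept is
#' the outcome mean.
#'
#' @param design A [design_matrix()] (or a list with \code{X}, \code{y}).
#' @param lambda1 L1 penalty (sparsity / feature selection), >= 0.
#' @param lambda2 L2 penalty (ridge-type smoothing), >= 0.
#' @param tol Convergence tolerance on max |coefficient change|.
#' @param max_sweeps Sweep budget; non-convergence is an error carrying the
#'   last iterate in \code{attr(, "last_iterate")}.
#' @param beta_init Optional warm start (standardized scale).
#' @param check_objective Assert the penalized objective is non-increasing
#'   across sweeps (debug mode).
#' @return Object of class \code{elastic_net_model} with the intercept and
#'   \code{beta} on the original feature scale (dropped zero-variance columns
#'   restored with coefficient 0), \code{beta_std} on the standardized scale,
#'   penalties, standardization parameters and \code{k} (nonzero count).
#' @export
fit_elastic_net <- function(design, lambda1 = 0, lambda2 = 0, tol = 1e-7,
                            max_sweeps = 30000, beta_init = NULL,
                            check_objective = FALSE) {
  if (!inherits(design, "design_matrix")) design <- design_matrix(design$X, design$y)
  if (lambda1 < 0 || lambda2 < 0) stop("penalties must be nonnegative")
  if (is.null(beta_init)) beta_init <- rep(0, ncol(design$Z))
  fit <- .enet_cd_gram_cpp(design$G, design$cxy, design$yty, lambda1, lambda2,
                           beta_init, tol, as.integer(max_sweeps),
                           check_objective)
  if (!fit$converged) {
    err <- simpleError(sprintf(
      "coordinate descent did not converge in %d sweeps (max delta %.3g)",
      max_sweeps, fit$max_delta))
    attr(err, "last_iterate") <- fit$beta
    stop(err)
  }
  beta_std_kept <- fit$beta
  p <- length(design$names)
  beta_std <- numeric(p)
  names(beta_std) <- design$names
  beta_std[design$keep] <- beta_std_kept
  beta_orig <- ifelse(design$keep, beta_std / design$scale, 0)
  intercept <- design$y_mean - sum(beta_orig * design$center)
  structure(list(
    intercept = intercept, beta = beta_orig, beta_std = beta_std,
    y_mean = design$y_mean, center = design$center, scale = design$scale,
    lambda1 = lambda1, lambda2 = lambda2,
    k = sum(beta_std != 0), dropped = design$names[!design$keep],
    converged = fit$converged, sweeps = fit$sweeps),
    class = "elastic_net_model")
}

#' @export
print.elastic_net_model <- function(x, ...) {
  cat(sprintf(
    "<elastic_net_model> %d/%d nonzero coefficients, lambda1=%.4g lambda2=%.4g, intercept=%.4f\n",
    x$k, length(x$beta), x$lambda1, x$lambda2, x$intercept))
  invisible(x)
}

#' Predict from an elastic-net model
#'
#' Linear score \code{intercept + X_new \%*\% beta} on the original feature
#' scale; identical to scoring standardized features with the standardized
#' coefficients.
#'
#' @param object An \code{elastic_net_model}.
#' @param newdata n x p matrix with the training columns (order or names
#'   must match).
#' @param ... Unused.
#' @return Numeric score vector.
#' @export
predict.elastic_net_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object$beta))
  if (!is.null(colnames(newdata)) && !is.null(names(object$beta))) {
    if (!setequal(colnames(newdata), names(object$beta)))
      stop("newdata column names do not match the model features")
    newdata <- newdata[, names(object$beta), drop = FALSE]
  }
  drop(object$intercept + newdata %*% object$beta)
}

#' Number of selected (nonzero) coefficients
#'
#' The k of the model's degrees-of-freedom pair k / (n - k - 1).
#'
#' @param model An \code{elastic_net_model}.
#' @return Integer count of strictly nonzero coefficients.
#' @export
count_selected <- function(model) {
  stopifnot(inherits(model, "elastic_net_model"))
  sum(model$beta_std != 0)
}

#' Choose both penalties by embedded cross-validation
#'
#' Grid search over \code{n_mix} mixing ratios \eqn{\alpha} (with
#' \eqn{\lambda_1 = \alpha \Lambda}, \eqn{\lambda_2 = (1-\alpha) \Lambda})
#' and a 50-point \eqn{\Lambda} ladder per ratio, log-spaced from the
#' smallest value that zeroes every coefficient down four decades, fitted
#' with warm starts. Folds are stratified on the outcome (sorted-cyclic
#' assignment after a seeded shuffle). The winning cell minimizes mean
#' held-out squared error; ties within 1e-12 go to the largest
#' \eqn{\lambda_1}, then the largest \eqn{\lambda_2} (sparsest, smoothest).
#'
#' @param design A [design_matrix()] or list with \code{X}, \code{y}.
#' @param n_folds Number of CV folds (default 10).
#' @param n_mix,n_lambda,decades Grid dimensions.
#' @param seed Integer seed for fold assignment.
#' @param max_retries Fold re-draws allowed when a training fold has constant
#'   outcome.
#' @return List of class \code{cv_result}: \code{grid} (one row per cell with
#'   mean CV error), \code{best} (chosen penalties), \code{model} (final fit
#'   on all data at the chosen penalties), \code{folds}, \code{seed}.
#' @export
cross_validate_penalties <- function(design, n_folds = 10, n_mix = 10,
                                     n_lambda = 50, decades = 4, seed = 1,
                                     max_retries = 5) {
  if (!inherits(design, "design_matrix")) design <- design_matrix(design$X, design$y)
  X <- sweep(sweep(design$Z, 2, design$scale[design$keep], "*"), 2,
             design$center[design$keep], "+")  # original scale, kept columns
  y <- design$yc + design$y_mean
  n <- length(y)
  if (n < n_folds || n_folds < 2) stop("need n >= n_folds >= 2")

  set.seed(seed)
  folds <- NULL
  for (try in seq_len(max_retries)) {
    ord <- order(y, stats::runif(n))        # outcome-stratified assignment
    f <- integer(n)
    f[ord] <- rep_len(seq_len(n_folds), n)
    ok <- all(vapply(seq_len(n_folds), function(k)
      stats::var(y[f != k]) > 0, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build folds with non-constant training outcome")

  alphas <- seq(1 / n_mix, 1, length.out = n_mix)
  lam1_kill <- 2 * max(abs(crossprod(design$Z, design$yc)))
  grid <- do.call(rbind, lapply(alphas, function(a) {
    Lmax <- lam1_kill / a
    L <- exp(seq(log(Lmax), log(Lmax) - decades * log(10),
                 length.out = n_lambda))
    data.frame(alpha = a, Lambda = L, lambda1 = a * L, lambda2 = (1 - a) * L)
  }))
  cv_err <- matrix(0, nrow(grid), n_folds)

  for (k in seq_len(n_folds)) {
    tr <- folds != k
    d_tr <- design_matrix(X[tr, , drop = FALSE], y[tr])
    X_te <- X[!tr, , drop = FALSE]
    y_te <- y[!tr]
    for (a in alphas) {
      idx <- which(grid$alpha == a)
      warm <- NULL
      for (i in idx) {
        fit <- fit_elastic_net(d_tr, grid$lambda1[i], grid$lambda2[i],
                               beta_init = warm)
        warm <- fit$beta_std[d_tr$keep]
        pred <- predict(fit, X_te)
        cv_err[i, k] <- mean((y_te - pred)^2)
      }
    }
  }
  grid$cv_error <- rowMeans(cv_err)
  best_err <- min(grid$cv_error)
  tied <- which(grid$cv_error <= best_err + 1e-12)
  tied <- tied[order(-grid$lambda1[tied], -grid$lambda2[tied])]
  best <- grid[tied[1], ]
  model <- fit_elastic_net(design, best$lambda1, best$lambda2)
  structure(list(grid = grid, best = best, model = model, folds = folds,
                 seed = seed), class = "cv_result")
}

#' Serialize an elastic-net model to JSON
#'
#' @param model An \code{elastic_net_model}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(list(
    intercept = model$intercept,
    beta = as.list(model$beta),
    lambda1 = model$lambda1, lambda2 = model$lambda2,
    center = as.list(model$center), scale = as.list(model$scale),
    k = count_selected(model)), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
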