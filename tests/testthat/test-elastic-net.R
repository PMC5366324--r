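random_problem <- function(n, p, seed, rho = 0.3, k = 3, snr = 2) {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p)
  X <- Z + rho * rowMeans(Z)  # mild column correlation
  colnames(X) <- paste0("f", seq_len(p))
  beta <- c(rnorm(k, sd = snr), rep(0, p - k))
  y <- drop(X %*% beta + rnorm(n))
  list(X = X, y = y)
}

test_that("the unpenalized limit reproduces ordinary least squares", {
  pr <- random_problem(150, 8, seed = 1)
  d <- design_matrix(pr$X, pr$y)
  fit <- fit_elastic_net(d, 0, 0, tol = 1e-10)
  ols <- stats::lm.fit(cbind(1, d$Z), pr$y)$coefficients[-1]
  expect_lt(sqrt(mean((fit$beta_std - ols)^2)), 1e-6)
  # fitted values match on the original scale too
  lmfit <- stats::lm(pr$y ~ pr$X)
  expect_equal(unname(predict(fit, pr$X)), unname(stats::fitted(lmfit)),
               tolerance = 1e-6)
})

test_that("the lasso-free limit reproduces closed-form ridge", {
  pr <- random_problem(120, 10, seed = 2)
  d <- design_matrix(pr$X, pr$y)
  for (l2 in c(5, 80)) {
    fit <- fit_elastic_net(d, 0, l2, tol = 1e-11)
    ridge <- solve(d$G + l2 * diag(ncol(d$Z)), d$cxy)
    expect_lt(sqrt(mean((fit$beta_std - ridge)^2)), 1e-6)
  }
})

test_that("a large enough L1 penalty kills every coefficient", {
  pr <- random_problem(100, 6, seed = 3)
  d <- design_matrix(pr$X, pr$y)
  kill <- 2 * max(abs(d$cxy))
  fit <- fit_elastic_net(d, kill, 0)
  expect_equal(unname(fit$beta), rep(0, 6))
  expect_equal(fit$intercept, mean(pr$y))
  expect_equal(count_selected(fit), 0)
  # strictly below the threshold something survives
  fit2 <- fit_elastic_net(d, 0.95 * kill, 0)
  expect_gt(count_selected(fit2), 0)
})

test_that("solutions agree with glmnet under the documented mapping", {
  skip_if_not_installed("glmnet")
  for (seed in 1:5) {
    pr <- random_problem(200, 12, seed = seed)
    d <- design_matrix(pr$X, pr$y)
    sy <- sqrt(mean(d$yc^2))
    n <- length(pr$y)
    for (pen in list(c(8, 0), c(8, 30), c(0, 30))) {
      fit <- fit_elastic_net(d, pen[1], pen[2], tol = 1e-12)
      lam <- (pen[1] + 2 * pen[2] * sy) / (2 * n)
      alpha <- pen[1] / (pen[1] + 2 * pen[2] * sy)
      g <- glmnet::glmnet(d$Z, d$yc, alpha = alpha, lambda = lam,
                          standardize = FALSE, intercept = FALSE,
                          thresh = 1e-14, maxit = 1e7)
      expect_lt(sqrt(mean((as.numeric(g$beta) - fit$beta_std)^2)), 1e-4)
    }
  }
})

test_that("the penalized objective never increases across sweeps", {
  pr <- random_problem(100, 15, seed = 4, rho = 0.8)
  d <- design_matrix(pr$X, pr$y)
  expect_s3_class(fit_elastic_net(d, 3, 1, check_objective = TRUE),
                  "elastic_net_model")
})

test_that("sparsity is monotone non-increasing along the L1 ladder", {
  pr <- random_problem(150, 12, seed = 5)
  d <- design_matrix(pr$X, pr$y)
  kill <- 2 * max(abs(d$cxy))
  ladder <- exp(seq(log(kill), log(kill) - 3 * log(10), length.out = 15))
  for (l2 in c(0, 10)) {
    ks <- vapply(ladder, function(l1)
      count_selected(fit_elastic_net(d, l1, l2)), numeric(1))
    expect_true(all(diff(ks) >= 0))  # ladder descends, k grows
  }
})

test_that("zero-variance columns are dropped and restored with zero weight", {
  pr <- random_problem(80, 5, seed = 6)
  X <- cbind(pr$X, const = 7)
  fit <- fit_elastic_net(design_matrix(X, pr$y), 1, 1)
  expect_equal(unname(fit$beta["const"]), 0)
  expect_equal(fit$dropped, "const")
  expect_length(fit$beta, 6)
  expect_error(design_matrix(cbind(X, NA), pr$y), "NA")
})

test_that("prediction validates the feature columns", {
  pr <- random_problem(60, 4, seed = 7)
  fit <- fit_elastic_net(design_matrix(pr$X, pr$y), 1, 1)
  expect_error(predict(fit, pr$X[, 1:3]), "columns")
  Xr <- pr$X[, c(3, 1, 2, 4)]  # permuted names are realigned
  expect_equal(predict(fit, Xr), predict(fit, pr$X))
})

test_that("non-convergence raises an error carrying the last iterate", {
  pr <- random_problem(100, 10, seed = 8, rho = 0.95)
  err <- tryCatch(
    fit_elastic_net(design_matrix(pr$X, pr$y), 0.1, 0, max_sweeps = 1),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_length(attr(err, "last_iterate"), 10)
})

test_that("cross-validation is deterministic and recovers planted support", {
  set.seed(20)
  n <- 240; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("f", 1:p)
  y <- drop(X[, 1:2] %*% c(3, -2) + rnorm(n, sd = 0.5))
  d <- design_matrix(X, y)
  cv1 <- cross_validate_penalties(d, seed = 77)
  cv2 <- cross_validate_penalties(d, seed = 77)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$best[, c("lambda1", "lambda2")],
                   cv2$best[, c("lambda1", "lambda2")])
  selected <- names(which(cv1$model$beta_std != 0))
  expect_true(all(c("f1", "f2") %in% selected))
  expect_equal(nrow(cv1$grid), 500)
  # the chosen cell attains the grid's minimal CV error
  expect_equal(cv1$best$cv_error, min(cv1$grid$cv_error))
})

test_that("pure-noise outcomes select near-zero feature counts most of the time", {
  # minimum-CV selection is known to admit a few spurious features under the
  # null; "near-zero" here means at most 2 of the 8 candidates
  hits <- 0
  for (run in 1:20) {
    set.seed(300 + run)
    X <- matrix(rnorm(1000 * 8), 1000, 8)
    y <- rnorm(1000)
    cv <- cross_validate_penalties(design_matrix(X, y), seed = run)
    if (count_selected(cv$model) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 16)  # >= 80% of runs
})

test_that("models serialize to JSON with their selection count", {
  pr <- random_problem(60, 4, seed = 9)
  fit <- fit_elastic_net(design_matrix(pr$X, pr$y), 2, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$k, count_selected(fit))
  expect_equal(unlist(back$beta), fit$beta, tolerance = 1e-12)
})
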