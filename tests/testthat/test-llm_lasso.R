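test_that("penalty transforms follow the power family with mean-1 rescaling", {
  expect_equal(transform_penalties(c(2, 8), 0), c(1, 1))
  expect_equal(transform_penalties(c(2, 8), 1), c(0.4, 1.6))
  expect_equal(transform_penalties(c(2, 8), 2), c(4, 64) / 34)
  expect_equal(transform_penalties(rep(3.7, 5), 4), rep(1, 5))
  for (phi in 0:5) {
    w <- transform_penalties(stats::runif(20, 0.1, 10), phi)
    expect_equal(mean(w), 1)
    expect_true(all(w > 0))
  }
  expect_error(transform_penalties(c(1, -1), 1), "positive")
  expect_error(transform_penalties(c(1, 2), 1.5), "integer")
})

test_that("a large enough lambda shrinks everything to the intercept", {
  set.seed(1)
  X <- matrix(stats::rnorm(60), 20, 3)
  Y <- stats::rnorm(20)
  W <- c(1, 2, 0.5)
  std <- sweep(sweep(X, 2, colMeans(X)), 2,
               sqrt(colSums(sweep(X, 2, colMeans(X))^2) / 20), "/")
  lam_max <- max(abs(crossprod(std, Y - mean(Y))) / W)
  fit <- weighted_lasso_fit(X, Y, lam_max * 1.01, W)
  expect_equal(unname(fit$beta), c(0, 0, 0))
  expect_equal(fit$intercept, mean(Y))
  expect_length(fit$support, 0L)
})

test_that("orthonormal designs reproduce the soft-threshold closed form", {
  for (seed in 1:10) {
    X <- orthonormal_design(30, 4, seed = seed)
    set.seed(seed + 100)
    Y <- stats::rnorm(30)
    W <- if (seed %% 2) rep(1, 4) else stats::runif(4, 0.5, 2)
    lam <- 0.3
    fit <- weighted_lasso_fit(X, Y, lam, W, standardize = FALSE)
    bols <- crossprod(X, Y - mean(Y))[, 1]       # X'X = I
    oracle <- sign(bols) * pmax(abs(bols) - lam * W, 0)
    expect_equal(unname(fit$beta_std), unname(oracle), tolerance = 1e-6)
  }
})

test_that("p = 2 fits match a brute-force grid minimizer of the objective", {
  grid_min <- function(Xc, yc, lam, W, lim = 2, nstep = 801) {
    b1 <- seq(-lim, lim, length.out = nstep)
    b2 <- b1
    s11 <- sum(Xc[, 1]^2); s22 <- sum(Xc[, 2]^2); s12 <- sum(Xc[, 1] * Xc[, 2])
    c1 <- sum(Xc[, 1] * yc); c2 <- sum(Xc[, 2] * yc)
    obj <- 0.5 * (outer(b1^2 * s11 - 2 * b1 * c1, b2^2 * s22 - 2 * b2 * c2, "+") +
                    2 * outer(b1, b2) * s12 + sum(yc^2)) +
      lam * outer(W[1] * abs(b1), W[2] * abs(b2), "+")
    min(obj)
  }
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(stats::rnorm(20), 10, 2)
    Y <- stats::rnorm(10)
    W <- stats::runif(2, 0.5, 2)
    lam <- stats::runif(1, 0.05, 0.5)
    fit <- weighted_lasso_fit(X, Y, lam, W, standardize = FALSE)
    Xc <- sweep(X, 2, colMeans(X)); yc <- Y - mean(Y)
    expect_lt(lasso_objective(fit, X, Y) - grid_min(Xc, yc, lam, W), 1e-6)
  }
})

test_that("unit weights reproduce an independent reference Lasso", {
  skip_if_not_installed("glmnet")
  for (seed in 1:6) {
    set.seed(seed)
    n <- 30; p <- 8
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- stats::rnorm(n)
    W <- if (seed %% 2) rep(1, p) else stats::runif(p, 0.5, 2)
    W <- W / mean(W)
    lam <- 2
    fit <- weighted_lasso_fit(X, Y, lam, W, standardize = FALSE)
    # glmnet objective is 1/(2n) RSS + lambda * sum pf_j |b_j|; penalty
    # factors are internally rescaled to sum to p (mean-1 W is unchanged)
    g <- glmnet::glmnet(X, Y, lambda = lam / n, penalty.factor = W,
                        standardize = FALSE, thresh = 1e-12)
    b_g <- as.numeric(g$beta)
    gap <- lasso_objective(fit, X, Y) -
      lasso_objective(fit, X, Y, beta_std = b_g)
    expect_lt(abs(gap), 1e-6)
  }
})

test_that("every converged fit carries a valid weighted KKT certificate", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- 25; p <- 10
    X <- matrix(stats::rnorm(n * p), n, p)
    Y <- stats::rnorm(n) + X[, 1] * 0.5
    W <- stats::runif(p, 0.3, 3)
    lam <- stats::runif(1, 0.5, 5)
    fit <- weighted_lasso_fit(X, Y, lam, W)
    expect_true(fit$converged)
    expect_lt(lasso_kkt_residual(fit, X, Y), 1e-5)
  }
})

test_that("raising one weight weakly shrinks that coefficient (orthonormal)", {
  X <- orthonormal_design(40, 3, seed = 5)
  set.seed(6)
  Y <- X %*% c(1, -0.8, 0.5) + stats::rnorm(40, 0, 0.2)
  lam <- 0.2
  prev <- Inf
  for (w2 in c(0.5, 1, 2, 4, 8)) {
    fit <- weighted_lasso_fit(X, Y, lam, c(1, w2, 1), standardize = FALSE)
    b2 <- abs(fit$beta_std[2])
    expect_lte(b2, prev + 1e-10)
    prev <- b2
  }
})

test_that("select_features orders by coefficient magnitude and flags emptiness", {
  fake <- structure(
    list(beta_std = c(0, 0.5, -0.2, 0), support_tol = 1e-8,
         beta = c(0, 0.5, -0.2, 0)),
    class = "weighted_lasso_fit")
  expect_equal(unname(select_features(fake)), c(2L, 3L))
  fake$beta_std <- rep(0, 4)
  expect_warning(sel <- select_features(fake), "empty support")
  expect_length(sel, 0L)
})

test_that("uniform scores make all exponents equivalent, ties resolve to phi 0", {
  f <- protocol_fixture(seed = 2, n_per_class = 15)
  uni <- penalty_scores(rep(2, ncol(f$dataset$X)))
  ts <- select_transform_cv(f$dataset$X, f$dataset$Y, uni, phi_grid = 0:3,
                            nlambda = 8, seed = 2)
  for (r in 2:nrow(ts$cv_losses)) {
    expect_equal(ts$cv_losses[r, ], ts$cv_losses[1, ], tolerance = 1e-10)
  }
  expect_identical(ts$phi_star, 0L)
})

test_that("transform selection keeps the worst-case guard and its bookkeeping", {
  f <- protocol_fixture(seed = 4)
  ts <- select_transform_cv(f$dataset$X, f$dataset$Y, f$scores,
                            nlambda = 12, seed = 4)
  expect_true(ts$guard_ok)
  expect_gte(ts$guard_margin, 0)
  expect_equal(ts$cv_loss_star, min(ts$cv_losses))
  expect_equal(dim(ts$cv_losses), c(length(ts$phi_grid), 12L))
  expect_true(ts$phi_star %in% ts$phi_grid)
  # chosen lambda belongs to the chosen phi's grid
  expect_true(ts$lam_star %in% ts$lambda_grids[[which(ts$phi_grid == ts$phi_star)]])
  # fold assignment is stratified and deterministic
  expect_identical(ts$fold_assignment,
                   stratified_folds(f$dataset$Y, 5, seed = 4))
  expect_error(select_transform_cv(f$dataset$X, f$dataset$Y, f$scores,
                                   phi_grid = 1:3), "phi_grid must contain 0")
})

test_that("stratification failures are reported", {
  expect_error(stratified_folds(c(0, 0, 0, 1, 1), 3), "stratification failure")
  folds <- stratified_folds(rep(c(0, 1), each = 10), 5, seed = 1)
  expect_true(all(table(folds, rep(c(0, 1), each = 10)) == 2))
})
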