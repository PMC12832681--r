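#' Power-transform penalty scores into Lasso weights
#'
#' Maps raw penalty scores to the weight vector actually used in the
#' weighted Lasso through the power family `w_j = s_j^phi`, then rescales
#' to mean 1 so that lambda grids stay comparable across exponents
#' without changing relative penalization. `phi = 0` gives exactly unit
#' weights — the plain Lasso — and larger exponents amplify the
#' knowledge-derived differences between edges.
#'
#' @param S A [penalty_scores()] or positive numeric vector.
#' @param phi Non-negative integer exponent.
#' @return Numeric weight vector with mean 1.
#' @export
#' @examples
#' transform_penalties(c(2, 8), 1)   # c(0.4, 1.6)
transform_penalties <- function(S, phi) {
  s <- as.numeric(S)
  if (any(s <= 0)) stop("transform_penalties: scores must be positive")
  if (length(phi) != 1L || phi < 0 || phi != round(phi)) {
    stop("transform_penalties: phi must be a non-negative integer")
  }
  if (phi == 0) return(rep(1, length(s)))
  w <- exp(phi * log(s))
  w / mean(w)
}

standardize_cols <- function(X, scale = TRUE) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  if (scale) {
    sds <- sqrt(colSums(Xc^2) / n)
    sds[sds < .Machine$double.eps] <- 1
    Xc <- sweep(Xc, 2, sds, "/")
  } else {
    sds <- rep(1, ncol(X))
  }
  list(Xc = Xc, center = ctr, scale = sds, colss = colSums(Xc^2))
}

#' Weighted Lasso fit by coordinate descent
#'
#' Minimizes `1/2 * sum_i (y_i - b0 - x_i'b)^2 + lam * sum_j w_j |b_j|`
#' by cyclic coordinate descent until the largest coefficient change in
#' a sweep falls below `tol`. Unit weights recover the plain Lasso.
#' Features are centered (and unit-scaled when `standardize = TRUE`)
#' internally; `beta` is reported on the original scale, `beta_std` on
#' the fitting scale used for support decisions, and the intercept is
#' unpenalized.
#'
#' @param X Numeric n x p matrix.
#' @param Y Numeric response; 0/1 class labels enter as reals.
#' @param lam Penalty level lambda (>= 0), on the scale of the
#'   un-normalized objective above.
#' @param W Positive penalty weights, recycled to length p (default 1).
#' @param standardize Unit-scale columns before fitting (default TRUE).
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @param support_tol Threshold on `|beta_std|` defining the support.
#' @return Object of class `weighted_lasso_fit` with elements `beta`,
#'   `beta_std`, `intercept`, `lam`, `weights`, `support`, `n_iter`,
#'   `converged`, `center`, `scale`.
#' @export
weighted_lasso_fit <- function(X, Y, lam, W = 1, standardize = TRUE,
                               tol = 1e-7, max_iter = 1e5,
                               support_tol = 1e-8) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  Y <- as.numeric(Y)
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("weighted_lasso_fit: non-finite values in X or Y")
  }
  if (nrow(X) != length(Y)) stop("weighted_lasso_fit: X rows != length(Y)")
  if (nrow(X) < 2) stop("weighted_lasso_fit: need n >= 2")
  if (length(lam) != 1L || lam < 0) stop("weighted_lasso_fit: lam must be >= 0")
  p <- ncol(X)
  W <- rep_len(as.numeric(W), p)
  if (any(W <= 0)) stop("weighted_lasso_fit: weights must be positive")
  std <- standardize_cols(X, scale = standardize)
  ybar <- mean(Y)
  yc <- Y - ybar
  res <- .cd_lasso_path(std$Xc, yc, W, lam, std$colss,
                        tol = tol, max_iter = as.integer(max_iter))
  b_std <- res$beta[, 1]
  beta <- b_std / std$scale
  intercept <- ybar - sum(std$center * beta)
  support <- which(abs(b_std) > support_tol)
  support <- support[order(abs(b_std[support]), decreasing = TRUE)]
  structure(
    list(beta = stats::setNames(beta, colnames(X)),
         beta_std = b_std, intercept = intercept, lam = lam, weights = W,
         support = support, n_iter = res$n_iter[1],
         converged = res$converged[1],
         center = std$center, scale = std$scale, support_tol = support_tol),
    class = "weighted_lasso_fit"
  )
}

#' @export
print.weighted_lasso_fit <- function(x, ...) {
  cat("Weighted Lasso fit: lambda = ", format(x$lam), ", ",
      length(x$support), " / ", length(x$beta),
      " features selected (", x$n_iter, " sweeps, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  invisible(x)
}

#' @rdname weighted_lasso_fit
#' @param fit A `weighted_lasso_fit`.
#' @param object_value Return the penalized objective instead of KKT
#'   residuals when TRUE.
#' @return `lasso_kkt_residual`: the largest violation of the weighted
#'   KKT stationarity conditions on the fitting (standardized) scale —
#'   `|g_j| <= lam*w_j` for zero coefficients and
#'   `g_j + lam*w_j*sign(b_j) = 0` for active ones, with `g` the gradient
#'   of the smooth part. Near zero for a converged fit.
#' @export
lasso_kkt_residual <- function(fit, X, Y) {
  X <- as.matrix(X)
  std_X <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  yc <- as.numeric(Y) - mean(Y)
  r <- yc - std_X %*% fit$beta_std
  g <- -crossprod(std_X, r)[, 1]
  lamw <- fit$lam * fit$weights
  zero <- abs(fit$beta_std) <= fit$support_tol
  viol_zero <- if (any(zero)) max(0, max(abs(g[zero]) - lamw[zero])) else 0
  act <- !zero
  viol_act <- if (any(act)) {
    max(abs(g[act] + lamw[act] * sign(fit$beta_std[act])))
  } else 0
  max(viol_zero, viol_act)
}

#' Penalized objective of a weighted Lasso fit
#'
#' Evaluates `1/2 * RSS + lam * sum_j w_j |b_j|` on the fitting scale,
#' for comparing solvers on identical problems.
#'
#' @inheritParams lasso_kkt_residual
#' @param beta_std,intercept0 Optional alternative coefficients on the
#'   fitting scale (defaults to the fit's own).
#' @export
lasso_objective <- function(fit, X, Y, beta_std = fit$beta_std,
                            intercept0 = NULL) {
  X <- as.matrix(X)
  std_X <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  yc <- as.numeric(Y) - mean(Y)
  r <- yc - std_X %*% beta_std
  0.5 * sum(r^2) + fit$lam * sum(fit$weights * abs(beta_std))
}

#' Lambda grid for the weighted Lasso
#'
#' Log-spaced grid of `nlambda` values from `lam_max` — the smallest
#' lambda with an all-zero solution, `max_j |x_j'(y - ybar)| / w_j` on
#' the fitting scale — down `decades` orders of magnitude.
#'
#' @inheritParams weighted_lasso_fit
#' @param nlambda Grid size.
#' @param decades Orders of magnitude spanned below `lam_max`.
#' @return Decreasing numeric vector.
#' @export
lambda_grid <- function(X, Y, W = 1, standardize = TRUE, nlambda = 20,
                        decades = 3) {
  X <- as.matrix(X)
  W <- rep_len(as.numeric(W), ncol(X))
  std <- standardize_cols(X, scale = standardize)
  yc <- as.numeric(Y) - mean(Y)
  lam_max <- max(abs(crossprod(std$Xc, yc))[, 1] / W)
  if (lam_max <= 0) lam_max <- 1
  exp(seq(log(lam_max), log(lam_max) - decades * log(10),
          length.out = nlambda))
}

cd_path_fit <- function(Xc, yc, colss, W, lambdas, tol = 1e-7,
                        max_iter = 1e5) {
  .cd_lasso_path(Xc, yc, W, lambdas, colss, tol = tol,
                 max_iter = as.integer(max_iter))
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of k folds, balancing classes; every fold
#' receives members of both classes or the split is rejected.
#'
#' @param Y 0/1 labels.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
stratified_folds <- function(Y, k, seed = 1) {
  Y <- as.integer(Y)
  if (k < 2) stop("stratified_folds: k must be >= 2")
  if (min(table(factor(Y, levels = c(0, 1)))) < k) {
    stop("stratified_folds: stratification failure - a class has fewer ",
         "than k = ", k, " members, some fold would be single-class")
  }
  folds <- integer(length(Y))
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(Y == cl)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

#' Cross-validated selection of the penalty-transform exponent
#'
#' Implements the guard that makes reliance on knowledge-derived scores
#' data-driven. For each exponent phi in `phi_grid` the scores are
#' mapped to weights by [transform_penalties()]; for each fold of a
#' k-fold stratified split, a weighted-Lasso path over a per-phi
#' [lambda_grid()] is fit on the training folds and scored on the
#' held-out fold. The (phi, lambda) cell minimizing the mean validation
#' loss is selected, with ties broken toward the smallest phi and then
#' the largest lambda (least knowledge dependence, sparsest model).
#' Because phi = 0 (unit weights, plain Lasso) is always in the grid,
#' the selected CV loss can never exceed the best plain-Lasso CV loss;
#' this invariant is asserted on every call. The final model is refit on
#' all data at the selected cell.
#'
#' @param X n x p feature matrix.
#' @param Y 0/1 labels.
#' @param S A [penalty_scores()] of length p.
#' @param phi_grid Integer exponents to consider; must contain 0.
#' @param nlambda Lambda-grid size per phi.
#' @param decades Lambda-grid span in orders of magnitude.
#' @param k Folds (default 5, stratified).
#' @param seed Seed for the fold split.
#' @param loss `"mse"` (squared error of the linear predictor against the
#'   0/1 labels, matching the squared-error fitting objective) or
#'   `"misclass"` (error rate of thresholding the predictor at 1/2).
#' @param standardize,tol,max_iter Passed to the solver.
#' @return Object of class `transform_selection`: `phi_grid`,
#'   `lambda_grids` (per phi), `cv_losses` (phi x lambda matrix of mean
#'   validation losses), `phi_star`, `lam_star`, `final_weights`,
#'   `fit` (full-data refit), `folds` = k, `fold_assignment`,
#'   `guard_ok`, `guard_margin` (best phi=0 loss minus selected loss).
#' @export
select_transform_cv <- function(X, Y, S, phi_grid = 0:5, nlambda = 20,
                                decades = 3, k = 5, seed = 1,
                                loss = c("mse", "misclass"),
                                standardize = TRUE, tol = 1e-7,
                                max_iter = 1e5) {
  loss <- match.arg(loss)
  X <- as.matrix(X); storage.mode(X) <- "double"
  Y <- as.numeric(Y)
  phi_grid <- sort(unique(as.integer(phi_grid)))
  if (!0L %in% phi_grid) {
    stop("select_transform_cv: phi_grid must contain 0 (the plain Lasso)")
  }
  p <- ncol(X)
  s <- as.numeric(S)
  if (length(s) != p) stop("select_transform_cv: scores length != p")
  folds <- stratified_folds(Y, k, seed)

  weights_by_phi <- lapply(phi_grid, function(ph) transform_penalties(s, ph))
  lambda_grids <- lapply(weights_by_phi, function(w) {
    lambda_grid(X, Y, w, standardize = standardize, nlambda = nlambda,
                decades = decades)
  })

  loss_fun <- function(pred, y) {
    if (loss == "mse") mean((pred - y)^2) else mean((pred >= 0.5) != (y == 1))
  }

  cv <- matrix(0, length(phi_grid), nlambda,
               dimnames = list(paste0("phi", phi_grid), NULL))
  for (fi in seq_len(k)) {
    tr <- folds != fi
    Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr]
    Xva <- X[!tr, , drop = FALSE]; Yva <- Y[!tr]
    std <- standardize_cols(Xtr, scale = standardize)
    yc <- Ytr - mean(Ytr)
    for (pi in seq_along(phi_grid)) {
      w <- weights_by_phi[[pi]]
      path <- cd_path_fit(std$Xc, yc, std$colss, w, lambda_grids[[pi]],
                          tol = tol, max_iter = max_iter)
      beta_orig <- path$beta / std$scale
      ints <- mean(Ytr) - crossprod(std$center, beta_orig)[1, ]
      pred <- Xva %*% beta_orig
      pred <- sweep(pred, 2, ints, "+")
      cv[pi, ] <- cv[pi, ] +
        vapply(seq_len(nlambda), function(li) loss_fun(pred[, li], Yva),
               numeric(1)) / k
    }
  }

  # argmin with tie-break: smallest phi, then largest lambda (lambda grids
  # are stored in decreasing order, so the smallest column index wins)
  best <- min(cv)
  cand <- which(cv <= best + 1e-12, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  pi_star <- cand[1, 1]; li_star <- cand[1, 2]
  phi_star <- phi_grid[pi_star]
  lam_star <- lambda_grids[[pi_star]][li_star]
  final_weights <- weights_by_phi[[pi_star]]

  best_phi0 <- min(cv[which(phi_grid == 0L), ])
  sel_loss <- unname(cv[pi_star, li_star])
  guard_margin <- best_phi0 - sel_loss
  if (sel_loss > best_phi0 + 1e-12) {
    stop("select_transform_cv: internal error - selected CV loss exceeds ",
         "the plain-Lasso optimum; the worst-case guard is violated")
  }

  fit <- weighted_lasso_fit(X, Y, lam_star, final_weights,
                            standardize = standardize, tol = tol,
                            max_iter = max_iter)
  structure(
    list(phi_grid = phi_grid, lambda_grids = lambda_grids, cv_losses = cv,
         phi_star = phi_star, lam_star = lam_star,
         cv_loss_star = sel_loss, cv_loss_phi0 = best_phi0,
         guard_ok = TRUE, guard_margin = guard_margin,
         final_weights = final_weights, fit = fit, folds = k,
         fold_assignment = folds, loss = loss, seed = seed),
    class = "transform_selection"
  )
}

#' @export
print.transform_selection <- function(x, ...) {
  cat("Penalty-transform selection over phi in {",
      paste(x$phi_grid, collapse = ", "), "}\n", sep = "")
  cat("  chosen phi* = ", x$phi_star, ", lambda* = ", format(x$lam_star),
      "\n", sep = "")
  cat("  CV loss ", format(x$cv_loss_star), " (plain-Lasso optimum ",
      format(x$cv_loss_phi0), ", guard margin ",
      format(x$guard_margin), ")\n", sep = "")
  cat("  ", length(x$fit$support), " features selected\n", sep = "")
  invisible(x)
}

#' Selected features of a weighted Lasso fit
#'
#' Indices with `|beta_std| > support_tol`, ordered by decreasing
#' coefficient magnitude on the fitting scale; these define the reduced
#' feature matrix handed to the classifier. An empty support is reported
#' with a warning rather than passed on silently.
#'
#' @param fit A [weighted_lasso_fit()] or [select_transform_cv()] result.
#' @param edge_map Optional [edge_index_map()] to attach edge names.
#' @return Integer vector of feature indices (possibly named).
#' @export
select_features <- function(fit, edge_map = NULL) {
  if (inherits(fit, "transform_selection")) fit <- fit$fit
  stopifnot(inherits(fit, "weighted_lasso_fit"))
  idx <- which(abs(fit$beta_std) > fit$support_tol)
  idx <- idx[order(abs(fit$beta_std[idx]), decreasing = TRUE)]
  if (!length(idx)) {
    warning("select_features: empty support - no feature passed the ",
            "threshold at this lambda")
    return(integer(0))
  }
  if (!is.null(edge_map)) names(idx) <- edge_map$names[idx]
  idx
}
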