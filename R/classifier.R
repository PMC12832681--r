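#' Train a linear max-margin classifier on selected edges
#'
#' Thin wrapper around a linear-kernel support-vector machine
#' (`e1071::svm`) exposing exactly the contract the counterfactual
#' engine needs: an affine, unscaled decision value ("logit")
#' `w'x + b` with prediction 1 iff the logit is >= 0. The weight vector
#' is re-oriented after training so that positive logits always mean
#' class 1 (normal control), regardless of which label the underlying
#' solver happened to treat as positive.
#'
#' @param Xq n x q matrix of selected features.
#' @param Y 0/1 labels (both classes required).
#' @param cost Soft-margin regularization constant (default 1).
#' @param feature_idx Optional indices of the q features in the parent
#'   dataset, recorded for provenance.
#' @return Object of class `margin_classifier` with `w` (length q),
#'   `b`, `cost`, `feature_idx`.
#' @export
train_margin_classifier <- function(Xq, Y, cost = 1, feature_idx = NULL) {
  Xq <- as.matrix(Xq); storage.mode(Xq) <- "double"
  Y <- as.integer(Y)
  if (length(unique(Y)) < 2L) {
    stop("train_margin_classifier: both classes must be present")
  }
  if (ncol(Xq) < 1L) stop("train_margin_classifier: need q >= 1 features")
  fit <- e1071::svm(x = Xq, y = factor(Y, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # decision values are positive for the class seen first in the training
  # data (fit$labels records that order), not for the first factor level
  first_class <- fit$levels[fit$labels[1]]
  if (as.character(first_class) == "0") { w <- -w; b <- -b }
  structure(
    list(w = as.numeric(w), b = as.numeric(b), cost = cost,
         feature_idx = feature_idx, n_train = nrow(Xq)),
    class = "margin_classifier"
  )
}

#' @export
print.margin_classifier <- function(x, ...) {
  cat("Linear margin classifier: q = ", length(x$w), " features, cost = ",
      x$cost, "\n", sep = "")
  invisible(x)
}

#' Unscaled decision value of a margin classifier
#'
#' @param model A [train_margin_classifier()] fit.
#' @param Xq Matrix (or single row) of feature values.
#' @return Numeric logits; prediction is 1 iff logit >= 0.
#' @export
classifier_logit <- function(model, Xq) {
  stopifnot(inherits(model, "margin_classifier"))
  if (is.null(dim(Xq))) Xq <- matrix(Xq, nrow = 1)
  drop(as.matrix(Xq) %*% model$w + model$b)
}

#' @export
predict.margin_classifier <- function(object, newdata, ...) {
  as.integer(classifier_logit(object, newdata) >= 0)
}

#' Confusion-matrix metrics with positives = normal controls
#'
#' Accuracy, sensitivity and specificity in percent, with label 1
#' (normal control) as the positive class — note that this is the
#' reverse of the clinical convention where the patient class is
#' positive. Zero-denominator rates are returned as `NaN` with a
#' warning.
#'
#' @param truth True 0/1 labels.
#' @param pred Predicted 0/1 labels.
#' @return Object of class `confusion_metrics`: list with counts `TP`,
#'   `TN`, `FP`, `FN` and percentages `acc`, `sen`, `spe`.
#' @export
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_metrics <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  TP <- sum(truth == 1L & pred == 1L)
  TN <- sum(truth == 0L & pred == 0L)
  FP <- sum(truth == 0L & pred == 1L)
  FN <- sum(truth == 1L & pred == 0L)
  acc <- 100 * (TP + TN) / (TP + TN + FP + FN)
  sen <- if (TP + FN == 0) {
    warning("confusion_metrics: no positives in truth, SEN undefined")
    NaN
  } else 100 * TP / (TP + FN)
  spe <- if (TN + FP == 0) {
    warning("confusion_metrics: no negatives in truth, SPE undefined")
    NaN
  } else 100 * TN / (TN + FP)
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 acc = acc, sen = sen, spe = spe),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("ACC %.2f%%  SEN %.2f%%  SPE %.2f%%  (TP %d, TN %d, FP %d, FN %d)\n",
              x$acc, x$sen, x$spe, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Evaluate a classifier on labelled data
#'
#' @inheritParams classifier_logit
#' @param Y True labels.
#' @return A [confusion_metrics()].
#' @export
evaluate_classifier <- function(model, Xq, Y) {
  confusion_metrics(Y, predict(model, Xq))
}

# Feature selection on one training set: transform-selection CV, then the
# full-data refit's support. If the chosen cell has an empty support, walk
# the chosen phi's lambda path downward to the largest lambda whose
# support is nonempty (deterministic fallback, recorded in the result).
select_on_training <- function(X, Y, S, phi_grid, nlambda, inner_k, seed,
                               ...) {
  ts <- select_transform_cv(X, Y, S, phi_grid = phi_grid, nlambda = nlambda,
                            k = inner_k, seed = seed, ...)
  sel <- suppressWarnings(select_features(ts))
  fallback <- FALSE
  if (!length(sel)) {
    fallback <- TRUE
    grid <- ts$lambda_grids[[which(ts$phi_grid == ts$phi_star)]]
    for (lam in grid[grid < ts$lam_star]) {
      f <- weighted_lasso_fit(X, Y, lam, ts$final_weights)
      if (length(f$support)) { ts$fit <- f; sel <- f$support; break }
    }
  }
  if (!length(sel)) {
    stop("select_on_training: no feature attains a nonzero coefficient ",
         "anywhere on the lambda path")
  }
  list(selection = ts, selected = sel, fallback = fallback)
}

#' k-fold protocol: selection + classification without leakage
#'
#' Full cross-validated evaluation of the pipeline. Within each of k
#' stratified outer folds, penalty-transform selection (itself an inner
#' CV on the training subjects only), the weighted-Lasso support, and
#' the SVM are all computed from the training folds; the held-out fold
#' is touched only at evaluation. Penalty scores are knowledge-derived
#' (independent of subject data) and therefore shared across folds.
#'
#' @param dataset An [fc_dataset()].
#' @param scores A [penalty_scores()] over the dataset's edges.
#' @param k Outer folds (default 5).
#' @param seed Seed controlling both fold splits.
#' @param phi_grid,nlambda,inner_k Passed to [select_transform_cv()].
#' @param cost SVM regularization.
#' @param ... Further arguments to [select_transform_cv()].
#' @return Object of class `kfold_result`: `per_fold` (list of
#'   [confusion_metrics()]), `mean` (averaged percentages), `selected`
#'   (per-fold selected edge indices), `phi_star` (per fold),
#'   `fold_assignment`, and `train_rows` (per-fold training indices, the
#'   leakage audit trail).
#' @export
kfold_protocol <- function(dataset, scores, k = 5, seed = 1,
                           phi_grid = 0:5, nlambda = 20, inner_k = 5,
                           cost = 1, ...) {
  stopifnot(inherits(dataset, "fc_dataset"))
  X <- dataset$X; Y <- dataset$Y
  folds <- stratified_folds(Y, k, seed)
  per_fold <- vector("list", k)
  selected <- vector("list", k)
  phi_star <- integer(k)
  train_rows <- vector("list", k)
  for (fi in seq_len(k)) {
    tr <- which(folds != fi); te <- which(folds == fi)
    train_rows[[fi]] <- tr
    res <- select_on_training(X[tr, , drop = FALSE], Y[tr], scores,
                              phi_grid, nlambda, inner_k,
                              seed = seed + fi, ...)
    sel <- res$selected
    model <- train_margin_classifier(X[tr, sel, drop = FALSE], Y[tr],
                                     cost = cost, feature_idx = sel)
    per_fold[[fi]] <- evaluate_classifier(model, X[te, sel, drop = FALSE],
                                          Y[te])
    selected[[fi]] <- sel
    phi_star[fi] <- res$selection$phi_star
  }
  agg <- function(f) mean(vapply(per_fold, `[[`, numeric(1), f))
  structure(
    list(per_fold = per_fold,
         mean = c(acc = agg("acc"), sen = agg("sen"), spe = agg("spe")),
         selected = selected, phi_star = phi_star,
         fold_assignment = folds, train_rows = train_rows, k = k,
         seed = seed),
    class = "kfold_result"
  )
}

#' @export
print.kfold_result <- function(x, ...) {
  cat(x$k, "-fold protocol: mean ACC ", sprintf("%.2f%%", x$mean["acc"]),
      ", SEN ", sprintf("%.2f%%", x$mean["sen"]),
      ", SPE ", sprintf("%.2f%%", x$mean["spe"]), "\n", sep = "")
  for (i in seq_len(x$k)) {
    cat(sprintf("  fold %d (phi* = %d, %d edges): ", i, x$phi_star[i],
                length(x$selected[[i]])))
    print(x$per_fold[[i]])
  }
  invisible(x)
}

#' Leave-one-dataset-out protocol
#'
#' Cross-site generalization: each dataset is held out once while
#' selection and classifier training use the pooled remaining datasets
#' only. All datasets must share an identical edge map.
#'
#' @param datasets List of >= 2 [fc_dataset()]s with identical edge maps.
#' @param scores Shared [penalty_scores()].
#' @param seed,phi_grid,nlambda,inner_k,cost,... As in
#'   [kfold_protocol()].
#' @return Object of class `lodo_result`: named list `per_dataset` of
#'   [confusion_metrics()], plus per-held-out selected edges and
#'   `phi_star`.
#' @export
leave_one_dataset_out <- function(datasets, scores, seed = 1,
                                  phi_grid = 0:5, nlambda = 20,
                                  inner_k = 5, cost = 1, ...) {
  if (length(datasets) < 2L) {
    stop("leave_one_dataset_out: need at least 2 datasets")
  }
  ref <- datasets[[1]]$edge_map
  for (d in datasets) {
    if (!identical(d$edge_map$names, ref$names)) {
      stop("leave_one_dataset_out: datasets have mismatched edge maps")
    }
  }
  nms <- vapply(datasets, `[[`, character(1), "dataset_name")
  per <- stats::setNames(vector("list", length(datasets)), nms)
  selected <- stats::setNames(vector("list", length(datasets)), nms)
  phi_star <- stats::setNames(integer(length(datasets)), nms)
  for (h in seq_along(datasets)) {
    rest <- datasets[-h]
    Xtr <- do.call(rbind, lapply(rest, `[[`, "X"))
    Ytr <- unlist(lapply(rest, `[[`, "Y"))
    res <- select_on_training(Xtr, Ytr, scores, phi_grid, nlambda, inner_k,
                              seed = seed + h, ...)
    sel <- res$selected
    model <- train_margin_classifier(Xtr[, sel, drop = FALSE], Ytr,
                                     cost = cost, feature_idx = sel)
    d <- datasets[[h]]
    per[[h]] <- evaluate_classifier(model, d$X[, sel, drop = FALSE], d$Y)
    selected[[h]] <- sel
    phi_star[h] <- res$selection$phi_star
  }
  structure(list(per_dataset = per, selected = selected,
                 phi_star = phi_star, seed = seed),
            class = "lodo_result")
}

#' @export
print.lodo_result <- function(x, ...) {
  cat("Leave-one-dataset-out protocol:\n")
  for (nm in names(x$per_dataset)) {
    cat("  held out ", nm, ": ", sep = "")
    print(x$per_dataset[[nm]])
  }
  invisible(x)
}
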