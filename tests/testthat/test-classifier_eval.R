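test_that("a separable toy is fit perfectly and logits flip with labels", {
  toy <- separable_toy()
  m <- train_margin_classifier(toy$X, toy$Y)
  expect_equal(predict(m, toy$X), toy$Y)
  expect_equal(evaluate_classifier(m, toy$X, toy$Y)$acc, 100)

  m_flip <- train_margin_classifier(toy$X, 1L - toy$Y)
  expect_equal(classifier_logit(m_flip, toy$X),
               -classifier_logit(m, toy$X), tolerance = 1e-6)
  expect_error(train_margin_classifier(toy$X, c(1, 1, 1, 1)),
               "both classes")
})

test_that("the hard-margin boundary on collinear points is the midpoint", {
  # class 0 at x = 0, class 1 at x = 2 and 4: max margin puts w x + b = 0
  # at the midpoint x = 1 of the closest opposite pair
  X <- matrix(c(0, 2, 4), ncol = 1)
  m <- train_margin_classifier(X, c(0L, 1L, 1L), cost = 1e4)
  boundary <- -m$b / m$w
  expect_equal(boundary, 1, tolerance = 0.02)
})

test_that("confusion metrics match hand arithmetic, positives = label 1", {
  truth <- c(rep(1, 13), rep(0, 11))
  pred <- c(rep(1, 12), 0, rep(0, 10), 1)   # TP 12, FN 1, TN 10, FP 1
  cm <- confusion_metrics(truth, pred)
  expect_equal(c(cm$TP, cm$FN, cm$TN, cm$FP), c(12, 1, 10, 1))
  expect_equal(cm$acc, 100 * 22 / 24)
  expect_equal(round(c(cm$acc, cm$sen, cm$spe), 2), c(91.67, 92.31, 90.91))

  cm2 <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(c(cm2$acc, cm2$sen, cm2$spe), c(100, 100, 100))

  expect_warning(cm3 <- confusion_metrics(c(0, 0), c(0, 1)), "SEN undefined")
  expect_true(is.nan(cm3$sen))

  # counts always partition the sample
  set.seed(8)
  for (i in 1:5) {
    tr <- stats::rbinom(30, 1, 0.5); pr <- stats::rbinom(30, 1, 0.5)
    cm <- suppressWarnings(confusion_metrics(tr, pr))
    expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 30)
  }
})

test_that("the k-fold protocol is accurate on strong signal and leak-free", {
  f <- protocol_fixture(seed = 11, effect_size = 3)
  kf <- kfold_protocol(f$dataset, f$scores, k = 5, seed = 11, nlambda = 10)
  expect_gte(kf$mean["acc"], 95)
  expect_equal(length(kf$per_fold), 5L)

  # deterministic fold assignment under the same seed
  kf2 <- kfold_protocol(f$dataset, f$scores, k = 5, seed = 11, nlambda = 10)
  expect_identical(kf$fold_assignment, kf2$fold_assignment)
  expect_identical(kf$selected, kf2$selected)

  # leakage audit: replaying selection on the recorded training rows of a
  # fold reproduces exactly the edge set used for that fold
  tr <- kf$train_rows[[3]]
  replay <- fclasso:::select_on_training(
    f$dataset$X[tr, , drop = FALSE], f$dataset$Y[tr], f$scores,
    phi_grid = 0:5, nlambda = 10, inner_k = 5, seed = 11 + 3)
  expect_identical(unname(replay$selected), unname(kf$selected[[3]]))
  # and the training rows exclude the evaluated fold
  expect_length(intersect(tr, which(kf$fold_assignment == 3)), 0L)
})

test_that("shuffled labels give chance-level cross-validated accuracy", {
  accs <- numeric(6)
  for (s in seq_along(accs)) {
    f <- protocol_fixture(seed = 30 + s, effect_size = 2, n_per_class = 30)
    d <- f$dataset
    set.seed(1000 + s)
    d$Y <- d$Y[sample.int(length(d$Y))]  # permuted labels
    kf <- try(kfold_protocol(d, f$scores, k = 5, seed = s, phi_grid = 0:2,
                             nlambda = 8), silent = TRUE)
    accs[s] <- if (inherits(kf, "try-error")) 50 else kf$mean["acc"]
  }
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("leave-one-dataset-out generalizes across synthetic sites", {
  sites <- lapply(1:3, function(s) {
    spec <- synthetic_spec(n_per_class = 30, N = 6,
                           signal_edges = c(2L, 7L, 11L), effect_size = 2.5,
                           seed = 100 + s)
    d <- generate_fc_dataset(spec, dataset_name = paste0("site", s))
    d
  })
  scores <- generate_penalty_scores(sites[[1]]$edge_map, c(2L, 7L, 11L),
                                    "informative", seed = 1)
  lodo <- leave_one_dataset_out(sites, scores, nlambda = 10)
  for (cm in lodo$per_dataset) expect_gt(cm$acc, 60)

  # a held-out site with flipped labels mirrors the unflipped accuracy
  flipped <- sites[[2]]
  flipped$Y <- 1L - flipped$Y
  flipped$dataset_name <- "site2flip"
  base <- leave_one_dataset_out(list(sites[[1]], sites[[2]]), scores,
                                nlambda = 10)
  flip <- leave_one_dataset_out(list(sites[[1]], flipped), scores,
                                nlambda = 10)
  expect_equal(flip$per_dataset$site2flip$acc,
               100 - base$per_dataset$site2$acc)

  expect_error(leave_one_dataset_out(sites[1], scores), "at least 2")
  odd <- generate_fc_dataset(synthetic_spec(n_per_class = 5, N = 5,
                                            signal_edges = 1L, seed = 1))
  expect_error(leave_one_dataset_out(list(sites[[1]], odd), scores),
               "mismatched edge maps")
})

test_that("duplicated datasets make held-out equal within-dataset training metrics", {
  f <- protocol_fixture(seed = 21, effect_size = 2, n_per_class = 25)
  d <- f$dataset
  d2 <- d; d2$dataset_name <- "copy"
  lodo <- leave_one_dataset_out(list(d, d2), f$scores, nlambda = 10)
  # training pool when 'copy' is held out is exactly d itself
  sel <- lodo$selected[["copy"]]
  m <- train_margin_classifier(d$X[, sel, drop = FALSE], d$Y)
  within <- evaluate_classifier(m, d$X[, sel, drop = FALSE], d$Y)
  expect_equal(lodo$per_dataset$copy$acc, within$acc)
  expect_equal(lodo$per_dataset$copy$sen, within$sen)
  expect_equal(lodo$per_dataset$copy$spe, within$spe)
})
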