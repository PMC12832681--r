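test_that("MAD computation matches the textbook definition with flooring", {
  M <- cbind(a = 1:5, b = c(-2, 0, 2, -2, 2), c = rep(7, 5))
  expect_warning(mads <- compute_mads(M), "floored")
  expect_equal(unname(mads[1]), 1)          # median |x - 3| over 1..5
  expect_equal(unname(mads[2]), 2)
  expect_equal(unname(mads[3]), 1e-3)       # constant column floored
  expect_equal(unname(compute_mads(cbind(c(-4, 0, 4)))[1]), 4)
  expect_error(compute_mads(matrix(1, 1, 2)), "n >= 2")
})

test_that("hinge loss follows the signed-target convention", {
  expect_equal(hinge_loss(2, 1), 0)
  expect_equal(hinge_loss(0.5, 1), 0.5)
  expect_equal(hinge_loss(-3, 0), 0)        # z = -1, z * logit = 3
  expect_equal(hinge_loss(1, 0), 2)
  expect_equal(hinge_loss(c(2, 0.5), 1), c(0, 0.5))
})

test_that("MAD distance is a mean over features, zero only at identity", {
  mads <- c(1, 1, 1, 1)
  m <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(mad_distance(m, m, mads), 0)
  x <- m; x[2] <- m[2] + 1                   # one feature moved by its MAD
  expect_equal(mad_distance(x, m, mads), 0.25)
  set.seed(2)
  a <- stats::runif(4); b <- stats::runif(4)
  expect_equal(mad_distance(a, b, mads), mad_distance(b, a, mads))
  expect_error(mad_distance(a, b[1:3], mads), "length mismatch")
})

test_that("determinantal diversity matches its closed forms", {
  mads <- c(1, 1)
  same <- rbind(c(0.1, 0.1), c(0.1, 0.1))
  expect_equal(diversity_det(same, mads, jitter_scale = 0), 0)
  expect_lt(abs(diversity_det(same, mads, jitter_scale = 1e-4, seed = 3)),
            1e-3)

  # two candidates at distance 1: K = [[1, .5], [.5, 1]], det 0.75
  pair <- rbind(c(0, 0), c(1, 1))            # mean(|1|/1, |1|/1) = 1
  expect_equal(diversity_det(pair, mads, jitter_scale = 0), 0.75)

  expect_equal(diversity_det(matrix(c(0.2, 0.3), 1), mads,
                             jitter_scale = 0), 1)

  # distances growing without bound push det toward 1
  far <- rbind(c(-500, -500), c(500, 500))
  expect_gt(diversity_det(far, mads, jitter_scale = 0), 0.99)
})

test_that("pure-validity optimization crosses the boundary for every candidate", {
  model <- linear_model(c(1, 1), 0)
  mads <- c(1, 1)
  cfg <- cf_config(L = 3, gamma1 = 0, gamma2 = 0, seed = 5,
                   bounds = c(-1, 1))
  cfs <- generate_counterfactuals(model, c(-0.5, -0.5), cfg, mads)
  expect_true(all(cfs$validity))
  expect_true(all(hinge_loss(cfs$logits, 1) < 1e-6))
  expect_true(all(cfs$candidates >= -1 & cfs$candidates <= 1))
  # validity flags agree exactly with the classifier prediction
  expect_equal(cfs$validity,
               predict(model, cfs$candidates) == cfg$target_label)
})

test_that("gamma1 improves proximity and gamma2 improves separation", {
  model <- linear_model(c(1, -0.5), 0.2)
  mads <- c(0.5, 0.5)
  m <- c(-0.6, 0.4)                          # logit -0.6: a patient-side point
  mean_dist <- function(cfs) {
    mean(apply(cfs$candidates[cfs$validity, , drop = FALSE], 1,
               mad_distance, m = m, mads = mads))
  }
  mean_pairwise <- function(cfs) {
    C <- cfs$candidates
    d <- 0; k <- 0
    for (u in 1:(nrow(C) - 1)) for (v in (u + 1):nrow(C)) {
      d <- d + mad_distance(C[u, ], C[v, ], mads); k <- k + 1
    }
    d / k
  }
  base <- cf_config(L = 4, gamma1 = 0, gamma2 = 0, seed = 7)
  prox <- cf_config(L = 4, gamma1 = 0.5, gamma2 = 0, seed = 7)
  divr <- cf_config(L = 4, gamma1 = 0.5, gamma2 = 1, seed = 7)
  cfs_base <- generate_counterfactuals(model, m, base, mads)
  cfs_prox <- generate_counterfactuals(model, m, prox, mads)
  cfs_divr <- generate_counterfactuals(model, m, divr, mads)
  expect_lt(mean_dist(cfs_prox), mean_dist(cfs_base))
  expect_gt(mean_pairwise(cfs_divr), mean_pairwise(cfs_prox))
})

test_that("the recorded objective trace is non-increasing", {
  model <- linear_model(c(0.8, 1.2), -0.1)
  cfg <- cf_config(L = 3, seed = 2, max_iters = 500)
  cfs <- generate_counterfactuals(model, c(-0.4, -0.7), cfg, c(0.3, 0.3))
  expect_true(all(diff(cfs$objective_trace) <= 1e-12))
})

test_that("generation, sparsification and reporting are seed-deterministic", {
  model <- linear_model(c(1, -1, 0.5), 0)
  mads <- c(0.4, 0.4, 0.4)
  m <- c(-0.5, 0.6, -0.2)
  run <- function() {
    cfs <- generate_counterfactuals(model, m, cf_config(L = 3, seed = 9), mads)
    sp <- sparsify_counterfactuals(cfs)
    diff_report(sp, c("e1", "e2", "e3"))
  }
  expect_identical(run(), run())
})

test_that("sparsification drops redundant changes and never invalidates", {
  model <- linear_model(c(1, 0), 0)          # second feature is irrelevant
  mads <- c(1, 1)
  cfs <- generate_counterfactuals(model, c(-0.5, 0),
                                  cf_config(L = 3, seed = 4), mads)
  expect_true(all(cfs$validity))
  # the optimizer perturbs both coordinates at least at initialization
  expect_true(any(vapply(cfs$diffs, function(d) 2 %in% d$feature, logical(1))))
  sp <- sparsify_counterfactuals(cfs)
  expect_true(all(sp$validity))
  for (d in sp$diffs) expect_false(2 %in% d$feature)

  # a candidate whose single change is necessary is returned unchanged
  one <- cfs
  one$candidates <- matrix(c(0.5, 0), 1)
  one$validity <- TRUE
  one$logits <- classifier_logit(model, one$candidates)
  one$diffs <- fclasso:::candidate_diffs(one)
  sp1 <- sparsify_counterfactuals(one, model)
  expect_equal(sp1$candidates, one$candidates)
})

test_that("diff reports carry values, directions and ranks", {
  model <- linear_model(c(1, 1), 0)
  cfs <- generate_counterfactuals(model, c(-0.2, -0.3),
                                  cf_config(L = 2, seed = 1), c(1, 1))
  # craft an exact one-edge change to check the formatting contract
  cfs$original <- c(-0.359, -0.3)
  cfs$candidates <- rbind(c(0.431, -0.3), c(-0.359, -0.3))
  cfs$logits <- classifier_logit(model, cfs$candidates)
  cfs$validity <- cfs$logits >= 0
  cfs$diffs <- fclasso:::candidate_diffs(cfs)
  rep <- diff_report(cfs, c("CAU.L--AMYG.R", "other"))
  row <- rep[rep$candidate == 1, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$edge, "CAU.L--AMYG.R")
  expect_equal(row$direction, "increase")
  expect_equal(row$delta, 0.79)
  # candidate 2 is unchanged: no rows
  expect_equal(nrow(rep[rep$candidate == 2, ]), 0L)
  expect_error(diff_report(cfs, "just-one-name"), "edge names")
})

test_that("an unreachable target is reported, not silently dropped", {
  model <- linear_model(c(0.01, 0.01), -10)  # logit can never reach 0 in box
  cfg <- cf_config(L = 2, seed = 3, max_iters = 50, n_restarts = 1)
  expect_warning(
    cfs <- generate_counterfactuals(model, c(0, 0), cfg, c(1, 1)),
    "no valid candidate")
  expect_false(any(cfs$validity))
  expect_equal(nrow(cfs$candidates), 2L)
})
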