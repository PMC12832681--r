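# shared fixture builders; everything is generated in code at test time

random_symmetric <- function(N, seed = 1, diag_value = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(N * N, -1, 1), N, N)
  A <- (A + t(A)) / 2
  diag(A) <- diag_value
  A
}

# n x p design with orthonormal, centered columns
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- sweep(X, 2, colMeans(X))
  qr.Q(qr(X))[, seq_len(p), drop = FALSE]
}

# linearly separable two-class toy in 2-D
separable_toy <- function() {
  X <- rbind(c(-1, -1), c(-1, -0.5), c(1, 1), c(1, 0.5))
  list(X = X, Y = c(0L, 0L, 1L, 1L))
}

# a hand-built linear classifier, bypassing SVM training
linear_model <- function(w, b) {
  structure(list(w = as.numeric(w), b = as.numeric(b), cost = 1,
                 feature_idx = NULL, n_train = NA_integer_),
            class = "margin_classifier")
}

# small dataset + informative scores used by several protocol tests
protocol_fixture <- function(seed = 1, effect_size = 2, n_per_class = 40,
                             N = 6) {
  spec <- synthetic_spec(n_per_class = n_per_class, N = N,
                         signal_edges = c(2L, 7L, 11L),
                         effect_size = effect_size, seed = seed)
  d <- generate_fc_dataset(spec)
  s <- generate_penalty_scores(d$edge_map, spec$signal_edges,
                               "informative", seed = seed)
  list(dataset = d, scores = s, spec = spec)
}
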