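#' Specification for a synthetic FC dataset
#'
#' Describes a two-group edge-feature simulation with a planted class
#' signal. Each edge j has a latent baseline mean; on the `signal_edges`
#' the normal-control group (label 1) is shifted by `effect_size` on the
#' latent (pre-squash) scale. Latent values are drawn as Gaussians with
#' standard deviation `noise_sd` and mapped into (-1, 1) by tanh, the
#' range of correlation-valued FC.
#'
#' Defaults are the package's reference simulation conditions: 60
#' subjects per class, 10 regions (45 edges), 5 signal edges, unit effect
#' size and unit noise; see the methods vignette for the rationale.
#'
#' @param n_per_class Subjects per class (>= 2). `n_class0` / `n_class1`
#'   override it to produce imbalance.
#' @param N Number of regions.
#' @param signal_edges Integer edge indices (1-based, see
#'   [edge_index_map()]) carrying the group difference. May be empty.
#' @param effect_size Latent-scale mean shift on signal edges (>= 0).
#' @param noise_sd Latent within-class standard deviation (> 0).
#' @param seed Integer seed; identical seeds give bit-identical data.
#' @param n_class0,n_class1 Optional per-class overrides.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 60, N = 10,
                           signal_edges = c(1L, 5L, 10L, 20L, 30L),
                           effect_size = 1, noise_sd = 1, seed = 1,
                           n_class0 = n_per_class, n_class1 = n_per_class) {
  N <- as.integer(N)
  p <- (N * (N - 1L)) %/% 2L
  signal_edges <- as.integer(signal_edges)
  if (length(signal_edges) && (any(signal_edges < 1L) || any(signal_edges > p))) {
    stop("synthetic_spec: signal_edges must lie in 1..", p)
  }
  if (anyDuplicated(signal_edges)) stop("synthetic_spec: duplicate signal edges")
  if (effect_size < 0) stop("synthetic_spec: effect_size must be >= 0")
  if (noise_sd <= 0) stop("synthetic_spec: noise_sd must be > 0")
  if (n_class0 < 2 || n_class1 < 2) {
    stop("synthetic_spec: need at least 2 subjects per class")
  }
  structure(
    list(n_class0 = as.integer(n_class0), n_class1 = as.integer(n_class1),
         N = N, p = p, signal_edges = signal_edges,
         effect_size = effect_size, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a synthetic FC dataset with a planted group signal
#'
#' Draws latent edge values `z ~ N(mu_j + shift, noise_sd)` where the
#' baseline means `mu_j ~ N(0, 0.2)` are fixed by the seed and `shift =
#' effect_size` only for class-1 subjects on the signal edges, then
#' squashes into (-1, 1) with `tanh`. The result emulates the edge-table
#' form the selection and counterfactual stages consume; it makes no
#' attempt to mimic real FC covariance structure or site effects.
#'
#' @param spec A [synthetic_spec()].
#' @param dataset_name Name recorded on the dataset.
#' @return An [fc_dataset()] with attribute `signal_edges` recording the
#'   planted ground truth.
#' @export
#' @examples
#' d <- generate_fc_dataset(synthetic_spec(n_per_class = 10, N = 5,
#'                                         signal_edges = c(1, 2), seed = 7))
#' dim(d$X)
generate_fc_dataset <- function(spec, dataset_name = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  em <- edge_index_map(spec$N)
  n0 <- spec$n_class0; n1 <- spec$n_class1
  n <- n0 + n1
  with_seed(spec$seed, {
    mu <- stats::rnorm(spec$p, 0, 0.2)
    Z <- matrix(stats::rnorm(n * spec$p, 0, spec$noise_sd), n, spec$p)
    Z <- sweep(Z, 2, mu, "+")
    if (length(spec$signal_edges)) {
      cls1 <- (n0 + 1):n
      Z[cls1, spec$signal_edges] <- Z[cls1, spec$signal_edges] + spec$effect_size
    }
    X <- tanh(Z)
    Y <- c(rep(0L, n0), rep(1L, n1))
    d <- fc_dataset(X, Y, em, dataset_name)
    attr(d, "signal_edges") <- spec$signal_edges
    d
  })
}

#' Generate synthetic per-edge penalty scores
#'
#' Emulates the score vector a knowledge provider would return, for
#' testing the transform-selection guard. `informative` gives strictly
#' smaller penalty factors to the signal edges than to all others (small
#' penalty = easy to select); `misleading` favours a random edge set
#' disjoint from the signal; `uniform` gives every edge the same factor,
#' making every power transform equivalent to the plain Lasso.
#'
#' @param edge_map An [edge_index_map()].
#' @param signal_edges Planted signal edge indices.
#' @param mode One of `"informative"`, `"misleading"`, `"uniform"`.
#' @param seed Integer seed.
#' @return A [penalty_scores()] object (all values strictly positive).
#' @export
generate_penalty_scores <- function(edge_map, signal_edges,
                                    mode = c("informative", "misleading",
                                             "uniform"),
                                    seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(edge_map, "edge_index_map"))
  p <- length(edge_map$names)
  signal_edges <- as.integer(signal_edges)
  with_seed(seed, {
    s <- stats::runif(p, 1, 3)
    if (mode == "informative") {
      s[signal_edges] <- stats::runif(length(signal_edges), 0.1, 0.3)
    } else if (mode == "misleading") {
      pool <- setdiff(seq_len(p), signal_edges)
      k <- min(length(signal_edges), length(pool))
      favored <- sample(pool, k)
      s[favored] <- stats::runif(k, 0.1, 0.3)
      attr(s, "favored") <- favored
    } else {
      s <- rep(1, p)
    }
    favored <- attr(s, "favored")
    names(s) <- edge_map$names
    ps <- penalty_scores(s, provenance = "mock")
    attr(ps, "favored") <- favored
    ps
  })
}
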