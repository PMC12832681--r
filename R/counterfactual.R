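#' Per-feature median absolute deviation with flooring
#'
#' Raw (unscaled) MAD per column, `median(|x - median(x)|)`, the robust
#' scale used to normalize counterfactual proximity. Zero or near-zero
#' MADs (constant features) are replaced by `floor` with a warning so
#' distances stay finite.
#'
#' @param Xq_train Training matrix of selected features (n >= 2).
#' @param floor Minimum admissible MAD (default 1e-3).
#' @return Numeric vector of strictly positive MADs with attribute
#'   `floored` marking replaced entries.
#' @export
#' @examples
#' compute_mads(cbind(a = 1:5, b = c(-2, 0, 2, -2, 2)))
compute_mads <- function(Xq_train, floor = 1e-3) {
  Xq_train <- as.matrix(Xq_train)
  if (nrow(Xq_train) < 2) stop("compute_mads: need n >= 2")
  m <- apply(Xq_train, 2, function(x) stats::median(abs(x - stats::median(x))))
  low <- m < floor
  if (any(low)) {
    warning("compute_mads: ", sum(low),
            " feature(s) with MAD below the floor ", floor, "; floored")
    m[low] <- floor
  }
  attr(m, "floored") <- low
  m
}

#' Hinge loss toward a target class
#'
#' `max(0, 1 - z * logit)` with `z = +1` when the target label is 1 and
#' `z = -1` when it is 0. Zero exactly when the candidate sits at or
#' beyond the unit margin on the target side.
#'
#' @param logit Unscaled classifier output(s).
#' @param target Target label, 0 or 1.
#' @return Nonnegative numeric of the same length as `logit`.
#' @export
hinge_loss <- function(logit, target) {
  z <- if (target == 1) 1 else -1
  pmax(0, 1 - z * logit)
}

#' MAD-normalized mean absolute distance
#'
#' `mean_alpha |x_alpha - m_alpha| / MAD_alpha` over the q features:
#' zero iff the vectors coincide, symmetric in its arguments.
#'
#' @param x,m Numeric vectors of equal length.
#' @param mads Positive per-feature MADs (see [compute_mads()]).
#' @return Nonnegative scalar.
#' @export
mad_distance <- function(x, m, mads) {
  if (length(x) != length(m) || length(x) != length(mads)) {
    stop("mad_distance: length mismatch (x ", length(x), ", m ", length(m),
         ", mads ", length(mads), ")")
  }
  mean(abs(x - m) / mads)
}

#' Determinantal diversity of a candidate set
#'
#' Builds the similarity kernel `K[u, v] = 1 / (1 + dist(x_u, x_v))`
#' from pairwise MAD-normalized distances and returns `det(K)`: near 0
#' when candidates duplicate each other, approaching 1 as they spread
#' apart. A seeded uniform jitter in `[0, jitter_scale]` is added to the
#' diagonal to keep near-singular kernels numerically stable; pass
#' `jitter_scale = 0` for the exact pre-jitter determinant.
#'
#' @param candidates L x q matrix, one candidate per row.
#' @param mads Per-feature MADs.
#' @param jitter_scale Upper bound of the diagonal jitter (default 1e-4).
#' @param seed Seed fixing the jitter within a run.
#' @return Scalar determinant.
#' @export
diversity_det <- function(candidates, mads, jitter_scale = 1e-4, seed = 1) {
  K <- diversity_kernel(candidates, mads, jitter_scale, seed)
  det(K)
}

diversity_kernel <- function(candidates, mads, jitter_scale = 1e-4,
                             seed = 1) {
  candidates <- as.matrix(candidates)
  L <- nrow(candidates)
  K <- diag(1, L)
  if (L > 1) {
    for (u in seq_len(L - 1)) {
      for (v in (u + 1):L) {
        K[u, v] <- K[v, u] <-
          1 / (1 + mad_distance(candidates[u, ], candidates[v, ], mads))
      }
    }
  }
  if (jitter_scale > 0) {
    jit <- with_seed(seed, stats::runif(L, 0, jitter_scale))
    diag(K) <- diag(K) + jit
  }
  K
}

#' Counterfactual-generation configuration
#'
#' Hyperparameters of the counterfactual objective and its optimizer.
#' Defaults follow the reference analysis settings: L = 5 candidates,
#' gamma1 = 0.5 (proximity weight), gamma2 = 1 (diversity weight),
#' target label 1 (patient -> normal control), and box bounds (-1, 1),
#' the range of correlation-valued FC.
#'
#' @param L Number of counterfactuals (>= 1).
#' @param gamma1 Weight of the mean MAD distance term (>= 0).
#' @param gamma2 Weight of the determinantal diversity term (>= 0).
#' @param target_label Desired predicted class, 0 or 1.
#' @param learning_rate Initial gradient step size.
#' @param max_iters Iteration cap per restart.
#' @param n_restarts Random restarts; the best run is kept.
#' @param seed Seed for initialization and jitter.
#' @param bounds Length-2 box bounds applied to every feature.
#' @param jitter_scale Diagonal jitter bound for the diversity kernel.
#' @param init_sd Standard deviation of the Gaussian initialization
#'   around the original example.
#' @return Object of class `cf_config`.
#' @export
cf_config <- function(L = 5, gamma1 = 0.5, gamma2 = 1, target_label = 1,
                      learning_rate = 0.05, max_iters = 2000,
                      n_restarts = 3, seed = 1, bounds = c(-1, 1),
                      jitter_scale = 1e-4, init_sd = 0.05) {
  if (L < 1) stop("cf_config: L must be >= 1")
  if (gamma1 < 0 || gamma2 < 0) stop("cf_config: gamma weights must be >= 0")
  if (!target_label %in% c(0, 1)) stop("cf_config: target_label must be 0 or 1")
  if (bounds[1] >= bounds[2]) stop("cf_config: invalid bounds")
  structure(
    list(L = as.integer(L), gamma1 = gamma1, gamma2 = gamma2,
         target_label = as.integer(target_label),
         learning_rate = learning_rate, max_iters = as.integer(max_iters),
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         bounds = as.numeric(bounds), jitter_scale = jitter_scale,
         init_sd = init_sd),
    class = "cf_config"
  )
}

cf_objective <- function(C, m, model, mads, config, K_jitter) {
  z <- if (config$target_label == 1) 1 else -1
  logits <- classifier_logit(model, C)
  hinge <- mean(pmax(0, 1 - z * logits))
  dist_term <- mean(apply(C, 1, mad_distance, m = m, mads = mads))
  K <- diversity_kernel(C, mads, jitter_scale = 0)
  diag(K) <- diag(K) + K_jitter
  hinge + config$gamma1 * dist_term - config$gamma2 * det(K)
}

cf_gradient <- function(C, m, model, mads, config, K_jitter) {
  L <- nrow(C); q <- ncol(C)
  z <- if (config$target_label == 1) 1 else -1
  G <- matrix(0, L, q)
  logits <- classifier_logit(model, C)
  active <- (1 - z * logits) > 0
  if (any(active)) {
    G[active, ] <- G[active, , drop = FALSE] +
      matrix(-z * model$w / L, sum(active), q, byrow = TRUE)
  }
  G <- G + config$gamma1 / L *
    sweep(sign(sweep(C, 2, m, "-")), 2, q * mads, "/")
  if (config$gamma2 > 0 && L > 1) {
    K <- diversity_kernel(C, mads, jitter_scale = 0)
    diag(K) <- diag(K) + K_jitter
    detK <- det(K)
    Kinv <- tryCatch(solve(K), error = function(e) NULL)
    if (!is.null(Kinv) && is.finite(detK)) {
      for (u in seq_len(L)) {
        gu <- numeric(q)
        for (v in seq_len(L)) {
          if (v == u) next
          dK <- -K[u, v]^2 * sign(C[u, ] - C[v, ]) / (q * mads)
          gu <- gu + 2 * detK * Kinv[u, v] * dK
        }
        G[u, ] <- G[u, ] - config$gamma2 * gu
      }
    }
  }
  G
}

#' Generate diverse counterfactual examples for one subject
#'
#' Jointly optimizes L candidate feature vectors against a trained
#' linear classifier by projected gradient descent on
#' `mean hinge + gamma1 * mean MAD-distance - gamma2 * det(K)`,
#' starting from seeded Gaussian perturbations of the original example
#' and clipping to the box bounds after every step. The step size is
#' halved whenever a step fails to decrease the objective, so the
#' recorded objective trace is non-increasing. Candidates whose final
#' prediction is not the target label are flagged invalid but kept.
#'
#' @param model A [train_margin_classifier()] fit.
#' @param m Original feature vector (within bounds).
#' @param config A [cf_config()].
#' @param mads Training-set MADs from [compute_mads()].
#' @return Object of class `counterfactual_set`: `original`,
#'   `candidates` (L x q), `validity`, `logits`, `objective_trace`,
#'   `diffs` (per-candidate data frame of changed features), `mads`,
#'   `config`, `sparsified`.
#' @export
generate_counterfactuals <- function(model, m, config = cf_config(), mads) {
  stopifnot(inherits(model, "margin_classifier"), inherits(config, "cf_config"))
  m <- as.numeric(m)
  q <- length(model$w)
  if (length(m) != q) stop("generate_counterfactuals: m has length ",
                           length(m), " but the model uses ", q, " features")
  if (any(m < config$bounds[1] - 1e-12) || any(m > config$bounds[2] + 1e-12)) {
    stop("generate_counterfactuals: original example outside the box bounds")
  }
  L <- config$L
  K_jitter <- with_seed(config$seed, stats::runif(L, 0, config$jitter_scale))

  run_restart <- function(r) {
    C <- with_seed(config$seed + 1000L * r, {
      matrix(m, L, q, byrow = TRUE) +
        matrix(stats::rnorm(L * q, 0, config$init_sd), L, q)
    })
    C <- pmin(pmax(C, config$bounds[1]), config$bounds[2])
    lr <- config$learning_rate
    obj <- cf_objective(C, m, model, mads, config, K_jitter)
    trace <- numeric(config$max_iters + 1L)
    trace[1] <- obj
    steps <- 0L
    for (it in seq_len(config$max_iters)) {
      G <- cf_gradient(C, m, model, mads, config, K_jitter)
      C_new <- pmin(pmax(C - lr * G, config$bounds[1]), config$bounds[2])
      obj_new <- cf_objective(C_new, m, model, mads, config, K_jitter)
      if (obj_new <= obj + 1e-12) {
        C <- C_new; obj <- obj_new
      } else {
        lr <- lr / 2
        if (lr < 1e-7) { steps <- it; break }
      }
      trace[it + 1L] <- obj
      steps <- it
    }
    logits <- classifier_logit(model, C)
    valid <- if (config$target_label == 1) logits >= 0 else logits < 0
    list(C = C, obj = obj, trace = trace[seq_len(steps + 1L)],
         logits = logits, valid = valid)
  }

  runs <- lapply(seq_len(config$n_restarts), run_restart)
  n_valid <- vapply(runs, function(r) sum(r$valid), integer(1))
  objs <- vapply(runs, `[[`, numeric(1), "obj")
  best <- order(-n_valid, objs)[1]
  r <- runs[[best]]
  if (sum(r$valid) == 0L) {
    warning("generate_counterfactuals: no valid candidate after ",
            config$n_restarts, " restarts; best logits: ",
            paste(format(r$logits, digits = 3), collapse = ", "))
  }
  cfs <- structure(
    list(original = m, candidates = r$C, validity = r$valid,
         logits = r$logits, objective_trace = r$trace,
         mads = mads, config = config, model = model,
         sparsified = FALSE),
    class = "counterfactual_set"
  )
  cfs$diffs <- candidate_diffs(cfs)
  cfs
}

candidate_diffs <- function(cf_set, tol = 1e-6) {
  lapply(seq_len(nrow(cf_set$candidates)), function(l) {
    x <- cf_set$candidates[l, ]
    m <- cf_set$original
    idx <- which(abs(x - m) > tol)
    nd <- abs(x - m)[idx] / cf_set$mads[idx]
    ord <- order(nd, decreasing = TRUE)
    data.frame(feature = idx[ord], before = m[idx][ord],
               after = x[idx][ord], delta = (x - m)[idx][ord],
               norm_delta = nd[ord])
  })
}

#' @export
print.counterfactual_set <- function(x, ...) {
  cat("Counterfactual set: L = ", nrow(x$candidates), ", ",
      sum(x$validity), " valid, target label ", x$config$target_label,
      if (x$sparsified) ", sparsified" else "", "\n", sep = "")
  for (l in seq_len(nrow(x$candidates))) {
    cat(sprintf("  candidate %d: logit %+.3f, %s, %d feature(s) changed\n",
                l, x$logits[l],
                if (x$validity[l]) "valid" else "INVALID",
                nrow(x$diffs[[l]])))
  }
  invisible(x)
}

#' Sparsify counterfactuals by greedy feature restoration
#'
#' Post-processing that shrinks each valid candidate's edit set: features
#' are restored to their original values one at a time in ascending
#' `|delta| / MAD` order, keeping a restoration only if the prediction
#' stays at the target label. Never invalidates a candidate and weakly
#' decreases the number of changed features; invalid candidates pass
#' through untouched.
#'
#' With `polish = TRUE`, each change that survives the restoration pass
#' is additionally shrunk toward the original value by bisection, to the
#' smallest magnitude that still keeps the candidate at the target
#' class: the minimal-change counterfactual along the retained edges.
#' Off by default so that the reported values show where the optimizer
#' actually placed the candidate relative to the margin.
#'
#' @param cf_set A [generate_counterfactuals()] result.
#' @param model The classifier used for generation (defaults to the one
#'   recorded in `cf_set`).
#' @param polish Bisect surviving changes down to the validity boundary.
#' @return The sparsified `counterfactual_set` (validity re-checked).
#' @export
sparsify_counterfactuals <- function(cf_set, model = cf_set$model,
                                     polish = FALSE) {
  stopifnot(inherits(cf_set, "counterfactual_set"))
  target <- cf_set$config$target_label
  ok <- function(x) {
    lg <- classifier_logit(model, x)
    if (target == 1) lg >= 0 else lg < 0
  }
  C <- cf_set$candidates
  for (l in seq_len(nrow(C))) {
    if (!cf_set$validity[l]) next
    x <- C[l, ]; m <- cf_set$original
    idx <- which(abs(x - m) > 0)
    if (!length(idx)) next
    ord <- idx[order(abs(x - m)[idx] / cf_set$mads[idx])]
    for (j in ord) {
      trial <- x
      trial[j] <- m[j]
      if (ok(trial)) x <- trial
    }
    if (polish) {
      for (j in which(abs(x - m) > 0)) {
        lo <- 0; hi <- 1   # fraction of the change retained
        for (it in seq_len(40)) {
          mid <- (lo + hi) / 2
          trial <- x
          trial[j] <- m[j] + mid * (x[j] - m[j])
          if (ok(trial)) hi <- mid else lo <- mid
        }
        x[j] <- m[j] + hi * (x[j] - m[j])
      }
    }
    C[l, ] <- x
  }
  cf_set$candidates <- C
  cf_set$logits <- classifier_logit(model, C)
  cf_set$validity <- if (target == 1) cf_set$logits >= 0 else cf_set$logits < 0
  cf_set$diffs <- candidate_diffs(cf_set)
  cf_set$sparsified <- TRUE
  cf_set
}

#' Per-edge difference report for a counterfactual set
#'
#' One row per changed edge per candidate: edge name, value before and
#' after, signed change, direction, and the MAD-normalized magnitude
#' used for ranking (largest changes first within each candidate).
#'
#' @param cf_set A `counterfactual_set`.
#' @param edge_names Names of the q features (e.g. the selected subset
#'   of an [edge_index_map()]'s names).
#' @return Data frame with columns `candidate`, `valid`, `edge`,
#'   `before`, `after`, `delta`, `direction`, `norm_delta`.
#' @export
diff_report <- function(cf_set, edge_names) {
  stopifnot(inherits(cf_set, "counterfactual_set"))
  q <- ncol(cf_set$candidates)
  if (length(edge_names) != q) {
    stop("diff_report: ", length(edge_names), " edge names for ", q,
         " features")
  }
  rows <- lapply(seq_along(cf_set$diffs), function(l) {
    d <- cf_set$diffs[[l]]
    if (!nrow(d)) return(NULL)
    data.frame(candidate = l, valid = cf_set$validity[l],
               edge = edge_names[d$feature],
               before = d$before, after = d$after, delta = d$delta,
               direction = ifelse(d$delta > 0, "increase", "decrease"),
               norm_delta = d$norm_delta)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(candidate = integer(0), valid = logical(0),
                      edge = character(0), before = numeric(0),
                      after = numeric(0), delta = numeric(0),
                      direction = character(0), norm_delta = numeric(0))
  }
  rownames(out) <- NULL
  out
}
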