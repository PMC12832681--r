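#' Pipeline run configuration
#'
#' Serializable description of a full offline run: where the data comes
#' from (a synthetic specification or an edge-table path), how penalty
#' scores are obtained, the selection and evaluation settings, the
#' counterfactual settings, and the output directory. A run is
#' reproducible from its archived configuration and seed alone.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master seed.
#' @param synthetic A [synthetic_spec()], or NULL to read `input_path`.
#' @param input_path Edge-table file when `synthetic` is NULL.
#' @param provider A [provider_config()].
#' @param phi_grid,nlambda,k Selection settings (see
#'   [select_transform_cv()]).
#' @param cost SVM regularization.
#' @param cf A [cf_config()].
#' @param cf_subject Row index of the subject to explain; the default
#'   `"first_patient"` picks the first patient predicted as a patient.
#' @param sparsify Run the post-hoc sparsification stage (default TRUE).
#' @param audience Explanation audience register.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("fclasso_run_"), seed = 1,
                       synthetic = synthetic_spec(seed = seed),
                       input_path = NULL,
                       provider = provider_config(seed = seed),
                       phi_grid = 0:5, nlambda = 20, k = 5, cost = 1,
                       cf = cf_config(seed = seed),
                       cf_subject = "first_patient",
                       sparsify = TRUE,
                       audience = "clinician") {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), synthetic = synthetic,
         input_path = input_path, provider = provider,
         phi_grid = phi_grid, nlambda = nlambda, k = k, cost = cost,
         cf = cf, cf_subject = cf_subject, sparsify = sparsify,
         audience = audience),
    class = "run_config"
  )
}

config_digest <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[setdiff(names(config), "out_dir")], tf)
  unname(tools::md5sum(tf))
}

#' Run the full pipeline offline
#'
#' Executes the seven stages end to end — simulate/ingest, score,
#' select, train, evaluate, counterfactual, explain — writing every
#' intermediate artifact under `config$out_dir` together with a JSON
#' manifest recording the stages, seeds, package version, and a hash of
#' the configuration. Any stage failure halts with the stage name; the
#' artifacts of completed stages remain on disk.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisible list with the dataset, scores, selection, model,
#'   metrics, counterfactual set, report, and manifest.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  say <- function(...) if (verbose) message("[fclasso] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  dataset <- stage("simulate", {
    if (!is.null(config$synthetic)) {
      d <- generate_fc_dataset(config$synthetic)
      write_fc_dataset(d, file.path(config$out_dir, "dataset.tsv"))
      truth <- attr(d, "signal_edges")
      writeLines(as.character(truth),
                 file.path(config$out_dir, "signal_edges.txt"))
      d
    } else {
      read_fc_dataset(config$input_path, "edge-table")
    }
  })

  scores <- stage("score", {
    s <- score_features(dataset, config = config$provider)
    write_penalty_scores(s, file.path(config$out_dir, "penalty_scores.tsv"))
    s
  })

  selection <- stage("select", {
    ts <- select_transform_cv(dataset$X, dataset$Y, scores,
                              phi_grid = config$phi_grid,
                              nlambda = config$nlambda, k = config$k,
                              seed = config$seed)
    sel <- suppressWarnings(select_features(ts, dataset$edge_map))
    report <- data.frame(
      rank = seq_along(sel),
      edge = dataset$edge_map$names[sel],
      beta = ts$fit$beta[sel],
      weight = ts$final_weights[sel])
    utils::write.table(report,
                       file.path(config$out_dir, "selected_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (ts$phi_star == 0 && attr(scores, "provenance") != "file") {
      say("guard activated: phi* = 0, knowledge scores left unused")
    }
    list(ts = ts, selected = sel)
  })
  if (!length(selection$selected)) {
    stop("pipeline halted at stage 'select': empty support")
  }

  model <- stage("train", {
    train_margin_classifier(dataset$X[, selection$selected, drop = FALSE],
                            dataset$Y, cost = config$cost,
                            feature_idx = selection$selected)
  })

  metrics <- stage("evaluate", {
    kf <- kfold_protocol(dataset, scores, k = config$k, seed = config$seed,
                         phi_grid = config$phi_grid,
                         nlambda = config$nlambda, cost = config$cost)
    tab <- data.frame(fold = seq_len(kf$k),
                      acc = vapply(kf$per_fold, `[[`, numeric(1), "acc"),
                      sen = vapply(kf$per_fold, `[[`, numeric(1), "sen"),
                      spe = vapply(kf$per_fold, `[[`, numeric(1), "spe"))
    utils::write.table(tab, file.path(config$out_dir, "cv_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    kf
  })

  cf_set <- stage("counterfactual", {
    Xq <- dataset$X[, selection$selected, drop = FALSE]
    mads <- suppressWarnings(compute_mads(Xq))
    subj <- config$cf_subject
    if (identical(subj, "first_patient")) {
      pred <- predict(model, Xq)
      cand <- which(dataset$Y == 0L & pred == 0L)
      subj <- if (length(cand)) cand[1] else which(dataset$Y == 0L)[1]
    }
    cfs <- generate_counterfactuals(model, Xq[subj, ], config$cf, mads)
    if (config$sparsify) cfs <- sparsify_counterfactuals(cfs)
    rep <- diff_report(cfs, dataset$edge_map$names[selection$selected])
    utils::write.table(rep,
                       file.path(config$out_dir, "counterfactual_diffs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    attr(cfs, "subject") <- subj
    cfs
  })

  report <- stage("explain", {
    req <- explanation_request(
      cf_set, dataset$edge_map$names[selection$selected],
      audience = config$audience)
    rp <- llm_explanation(req, config$provider)
    writeLines(rp$summary, file.path(config$out_dir, "explanation.txt"))
    rp
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fclasso")),
    seed = config$seed,
    config_hash = config_digest(config),
    stages = stages,
    phi_star = selection$ts$phi_star,
    lambda_star = selection$ts$lam_star,
    guard_activated = selection$ts$phi_star == 0,
    n_selected = length(selection$selected),
    selected_edges = dataset$edge_map$names[selection$selected],
    mean_metrics = as.list(metrics$mean),
    cf_subject = attr(cf_set, "subject"),
    cf_valid = sum(cf_set$validity))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: ", length(stages), " stages, artifacts in ", config$out_dir)
  invisible(list(dataset = dataset, scores = scores,
                 selection = selection$ts, selected = selection$selected,
                 model = model, metrics = metrics, cf_set = cf_set,
                 report = report, manifest = manifest))
}
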