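#' Per-edge penalty scores
#'
#' Container for the strictly positive per-feature penalty factors
#' `s_1..s_p` that weight the L1 penalty: smaller values make an edge
#' easier to select. Scores come from a text-generation provider, a
#' scores file, or the deterministic mock.
#'
#' @param values Numeric vector of strictly positive scores, ideally
#'   named by edge.
#' @param provenance One of `"llm"`, `"file"`, `"mock"`.
#' @param raw_response_hash Optional hash of the raw provider output.
#' @return Object of class `penalty_scores`.
#' @export
penalty_scores <- function(values, provenance = c("mock", "llm", "file"),
                           raw_response_hash = NA_character_) {
  provenance <- match.arg(provenance)
  nms <- names(values)
  values <- as.numeric(values)
  names(values) <- nms
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("penalty_scores: all scores must be finite and strictly positive")
  }
  structure(values, class = "penalty_scores", provenance = provenance,
            raw_response_hash = raw_response_hash)
}

#' @export
print.penalty_scores <- function(x, ...) {
  cat("Penalty scores: p = ", length(x), ", provenance = ",
      attr(x, "provenance"), "\n", sep = "")
  cat("range [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  invisible(x)
}

#' Prompt specification for penalty elicitation
#'
#' The rendered prompt is a pure function of these fields: a background /
#' task description, the feature (edge) names to score, the contrast
#' category (e.g. "schizophrenia vs normal control"), and a system
#' context shared across chunks.
#'
#' @param task_description Background and task text.
#' @param feature_names Non-empty character vector of edge names.
#' @param category Text naming the classification contrast.
#' @param system_context System-role text.
#' @return Object of class `prompt_spec`.
#' @export
prompt_spec <- function(task_description, feature_names, category,
                        system_context = paste(
                          "You are a neuroscience expert assigning penalty",
                          "factors for feature selection.")) {
  if (!length(feature_names)) stop("prompt_spec: feature_names is empty")
  structure(
    list(task_description = task_description,
         feature_names = as.character(feature_names),
         category = category,
         system_context = system_context),
    class = "prompt_spec"
  )
}

#' Default prompt spec for an FC dataset
#'
#' @param dataset An [fc_dataset()].
#' @param category Contrast description.
#' @return A [prompt_spec()] over the dataset's edge names.
#' @export
fc_prompt_spec <- function(dataset,
                           category = "schizophrenia vs normal control") {
  prompt_spec(
    task_description = paste(
      "Each feature is the resting-state functional connectivity between",
      "two brain regions. Rate how strongly each connection's abnormality",
      "is implicated in the contrast, and return a PENALTY factor per",
      "feature: smaller penalties for connections with stronger evidence",
      "of involvement (they should be easier to select), larger penalties",
      "otherwise."),
    feature_names = dataset$edge_map$names,
    category = category
  )
}

#' Provider configuration
#'
#' Configures how penalty scores are obtained. `provider` is either the
#' built-in `"mock"` (deterministic, offline), `"file"` (read a scores
#' file, bypassing prompting), or a function `function(prompt) -> text`
#' supplied via `provider_fun` for live endpoints; in that case
#' `provider_name` keys the cache. Temperature defaults to 0 (greedy
#' decoding) so that repeated queries are reproducible.
#'
#' @param provider `"mock"` or `"file"`.
#' @param provider_fun Optional function mapping prompt text to response
#'   text; overrides `provider`.
#' @param provider_name Cache key for a custom provider.
#' @param temperature Sampling temperature requested from the provider.
#' @param chunk_size Edges scored per prompt.
#' @param cache_dir Optional directory for response caching.
#' @param seed Seed for the mock provider.
#' @param scores_file Path to a two-column scores file (`"file"` mode).
#' @param score_floor,score_cap Clipping range enforced on parsed scores.
#' @return Object of class `provider_config`.
#' @export
provider_config <- function(provider = c("mock", "file"),
                            provider_fun = NULL,
                            provider_name = NULL,
                            temperature = 0,
                            chunk_size = 200L,
                            cache_dir = NULL,
                            seed = 1L,
                            scores_file = NULL,
                            score_floor = 1e-3,
                            score_cap = 1e3) {
  if (is.null(provider_fun)) provider <- match.arg(provider) else provider <- "custom"
  if (provider == "file" && is.null(scores_file)) {
    stop("provider_config: 'file' provider needs scores_file")
  }
  if (is.null(provider_name)) provider_name <- provider
  structure(
    list(provider = provider, provider_fun = provider_fun,
         provider_name = provider_name, temperature = temperature,
         chunk_size = as.integer(chunk_size), cache_dir = cache_dir,
         seed = as.integer(seed), scores_file = scores_file,
         score_floor = score_floor, score_cap = score_cap),
    class = "provider_config"
  )
}

#' Build a penalty-elicitation prompt for one chunk of edge names
#'
#' Deterministic rendering of the full prompt: system context, task
#' description, category, a delimited feature block listing each chunk
#' name exactly once, and a machine-readable output-format instruction
#' (one `name<TAB>score` line per feature).
#'
#' @param spec A [prompt_spec()].
#' @param chunk Character vector of feature names to score (subset of
#'   `spec$feature_names`).
#' @return Single prompt string.
#' @export
build_penalty_prompt <- function(spec, chunk = spec$feature_names) {
  stopifnot(inherits(spec, "prompt_spec"))
  if (!length(chunk)) stop("build_penalty_prompt: empty chunk")
  paste0(
    "[SYSTEM]\n", spec$system_context, "\n\n",
    "[TASK]\n", spec$task_description, "\n",
    "Classification contrast: ", spec$category, ".\n\n",
    "[FEATURES]\n",
    paste(chunk, collapse = "\n"),
    "\n[END FEATURES]\n\n",
    "[FORMAT]\n",
    "Return exactly one line per feature, in the order given, as\n",
    "<feature name><TAB><penalty score>\n",
    "where the penalty score is a positive number in [0.001, 1000];\n",
    "smaller means the connection is more strongly implicated. No other text.\n"
  )
}

# deterministic 31-adic rolling hash of a string, in [0, 2^31 - 2]
name_hash <- function(s) {
  m <- 2147483647
  vapply(s, function(one) {
    h <- 0
    for (b in utf8ToInt(one)) h <- (h * 31 + b) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic mock provider
#'
#' Answers a penalty-elicitation prompt offline: the feature names are
#' read back from the prompt's `[FEATURES]` block and each receives a
#' strictly positive score derived from a seeded hash of its name, so the
#' same (name, seed) always yields the same score. Scores are log-uniform
#' in [0.1, 10].
#'
#' @param prompt Prompt text produced by [build_penalty_prompt()].
#' @param config A [provider_config()]; only `seed` is used.
#' @return Response text in the requested `name<TAB>score` format.
#' @export
mock_provider <- function(prompt, config = provider_config()) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  a <- which(lines == "[FEATURES]")
  b <- which(lines == "[END FEATURES]")
  if (length(a) != 1L || length(b) != 1L || b <= a + 1L) {
    stop("mock_provider: prompt has no [FEATURES] block")
  }
  nms <- lines[(a + 1L):(b - 1L)]
  h <- name_hash(paste0(nms, "#", config$seed))
  u <- ((h %% 100000) + 0.5) / 100000      # deterministic uniform in (0,1)
  score <- 10 ^ (2 * u - 1)                # log-uniform in [0.1, 10]
  paste0(nms, "\t", formatC(score, digits = 6, format = "g"),
         collapse = "\n")
}

#' Parse a provider response into scores
#'
#' Strict validation against hallucinated or malformed output: every
#' expected name must receive exactly one numeric score (first occurrence
#' wins, duplicates warned); unknown names are ignored with a warning;
#' non-positive, non-finite, or out-of-range scores are clipped into
#' `[floor, cap]` with a warning. A missing expected name or an
#' unparseable structure is a hard error naming the first offender, so
#' the caller can retry the chunk.
#'
#' @param text Provider output.
#' @param expected_names Names that must each receive a score.
#' @param floor,cap Clipping range.
#' @return Named numeric vector of scores over `expected_names`.
#' @export
parse_penalty_response <- function(text, expected_names,
                                   floor = 1e-3, cap = 1e3) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  got <- stats::setNames(rep(NA_real_, length(expected_names)), expected_names)
  for (ln in lines) {
    parts <- strsplit(ln, "[\t,:]+")[[1]]
    if (length(parts) < 2L) next
    nm <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(parts[length(parts)])))
    if (!nm %in% expected_names) {
      warning("parse_penalty_response: ignoring unknown feature '", nm, "'")
      next
    }
    if (!is.na(got[nm])) {
      warning("parse_penalty_response: duplicate score for '", nm,
              "', keeping the first")
      next
    }
    if (is.na(val)) {
      stop("parse_penalty_response: non-numeric score for '", nm, "'")
    }
    if (!is.finite(val) || val < floor || val > cap) {
      clipped <- min(max(val, floor), cap)
      if (!is.finite(val) || val <= 0) clipped <- floor
      warning("parse_penalty_response: score ", val, " for '", nm,
              "' clipped to ", clipped)
      val <- clipped
    }
    got[nm] <- val
  }
  if (anyNA(got)) {
    stop("parse_penalty_response: missing score for '",
         names(got)[which(is.na(got))[1]], "'")
  }
  got
}

cache_key <- function(prompt, provider_name) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(provider_name, prompt), tf)
  unname(tools::md5sum(tf))
}

#' Read and write penalty-scores files
#'
#' Tab-delimited, two columns with header: `edge` (name) and `score`.
#'
#' @param path File path.
#' @return `read_penalty_scores`: a [penalty_scores()] with provenance
#'   `"file"`.
#' @export
read_penalty_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("edge", "score") %in% names(df))) {
    stop("read_penalty_scores: file must have 'edge' and 'score' columns")
  }
  penalty_scores(stats::setNames(as.numeric(df$score), df$edge),
                 provenance = "file")
}

#' @rdname read_penalty_scores
#' @param scores A [penalty_scores()] (or named numeric vector).
#' @export
write_penalty_scores <- function(scores, path) {
  df <- data.frame(edge = names(scores), score = as.numeric(scores))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Score all edges of a dataset
#'
#' Assembles the full-length penalty-score vector by querying the
#' configured provider in chunks of `chunk_size` edge names, parsing and
#' validating each response, and concatenating in dataset edge order.
#' Responses are cached on disk keyed by (provider name, prompt text)
#' when `cache_dir` is set, so a rerun issues zero provider calls. The
#' `"file"` provider bypasses prompting entirely and reads
#' `scores_file`, reordered to the dataset's edges.
#'
#' @param dataset An [fc_dataset()].
#' @param spec A [prompt_spec()]; defaults to [fc_prompt_spec()].
#' @param config A [provider_config()].
#' @return A [penalty_scores()] of length p, aligned with the dataset's
#'   edge order.
#' @export
score_features <- function(dataset, spec = fc_prompt_spec(dataset),
                           config = provider_config()) {
  stopifnot(inherits(dataset, "fc_dataset"))
  nms <- dataset$edge_map$names
  if (config$provider == "file") {
    sc <- read_penalty_scores(config$scores_file)
    missing <- setdiff(nms, names(sc))
    if (length(missing)) {
      stop("score_features: scores file lacks edge '", missing[1], "'")
    }
    vals <- as.numeric(sc)[match(nms, names(sc))]
    vals <- pmin(pmax(vals, config$score_floor), config$score_cap)
    return(penalty_scores(stats::setNames(vals, nms), provenance = "file"))
  }
  ask <- if (config$provider == "custom") config$provider_fun else {
    function(prompt) mock_provider(prompt, config)
  }
  chunks <- split(nms, ceiling(seq_along(nms) / config$chunk_size))
  n_calls <- 0L
  pieces <- lapply(chunks, function(ch) {
    prompt <- build_penalty_prompt(spec, ch)
    resp <- NULL
    cache_file <- NULL
    if (!is.null(config$cache_dir)) {
      if (!dir.exists(config$cache_dir)) {
        dir.create(config$cache_dir, recursive = TRUE)
      }
      key <- cache_key(prompt, paste0(config$provider_name, "#", config$seed))
      cache_file <- file.path(config$cache_dir, paste0(key, ".txt"))
      if (file.exists(cache_file)) {
        resp <- paste(readLines(cache_file), collapse = "\n")
      }
    }
    if (is.null(resp)) {
      resp <- ask(prompt)
      n_calls <<- n_calls + 1L
      if (!is.null(cache_file)) writeLines(resp, cache_file)
    }
    parse_penalty_response(resp, ch, config$score_floor, config$score_cap)
  })
  vals <- unlist(unname(pieces))
  vals <- vals[nms]
  prov <- if (config$provider == "mock") "mock" else "llm"
  out <- penalty_scores(vals, provenance = prov)
  attr(out, "provider_calls") <- n_calls
  out
}
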