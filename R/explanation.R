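#' Explanation request from a counterfactual set
#'
#' Packages everything an explanation needs: the subject's original edge
#' values, each candidate's per-edge changes, the edge names, and the
#' intended audience register.
#'
#' @param cf_set A [generate_counterfactuals()] result (sparsified or
#'   not).
#' @param edge_names Names of the q features.
#' @param audience `"clinician"` or `"patient"`.
#' @return Object of class `explanation_request`.
#' @export
explanation_request <- function(cf_set, edge_names,
                                audience = c("clinician", "patient")) {
  audience <- match.arg(audience)
  stopifnot(inherits(cf_set, "counterfactual_set"))
  if (length(edge_names) != ncol(cf_set$candidates)) {
    stop("explanation_request: edge_names length mismatch")
  }
  structure(
    list(original = stats::setNames(cf_set$original, edge_names),
         diffs = cf_set$diffs, validity = cf_set$validity,
         edge_names = edge_names, audience = audience),
    class = "explanation_request"
  )
}

#' Build an explanation prompt
#'
#' Deterministic prompt embedding the original edge values, one option
#' block per candidate listing its changes (or "no change required" for
#' an empty diff), and instructions to rank the options by effectiveness
#' and feasibility in plain language.
#'
#' @param req An [explanation_request()].
#' @return Single prompt string.
#' @export
build_explanation_prompt <- function(req) {
  stopifnot(inherits(req, "explanation_request"))
  for (d in req$diffs) {
    if (nrow(d) && any(d$feature > length(req$edge_names))) {
      stop("build_explanation_prompt: diff references unknown edge index ",
           d$feature[d$feature > length(req$edge_names)][1])
    }
  }
  orig <- paste0("  ", req$edge_names, " = ",
                 formatC(req$original, digits = 3, format = "f"),
                 collapse = "\n")
  blocks <- vapply(seq_along(req$diffs), function(l) {
    d <- req$diffs[[l]]
    head <- paste0("OPTION ", l,
                   if (!req$validity[l]) " (did not reach the target class)"
                   else "", ":\n")
    body <- if (!nrow(d)) "  no change required\n" else {
      paste0("  ", ifelse(d$delta > 0, "increase", "decrease"),
             " connectivity ", req$edge_names[d$feature], " from ",
             formatC(d$before, digits = 3, format = "f"), " to ",
             formatC(d$after, digits = 3, format = "f"),
             collapse = "\n")
    }
    paste0(head, body, "\n")
  }, character(1))
  paste0(
    "[SYSTEM]\nYou explain brain-connectivity model outputs in simple, ",
    "plain language for a ", req$audience, ".\n\n",
    "[ORIGINAL FUNCTIONAL CONNECTIVITY VALUES]\n", orig, "\n\n",
    "[COUNTERFACTUAL OPTIONS]\n", paste(blocks, collapse = "\n"),
    "\n[TASK]\nEach option lists connectivity adjustments that would move ",
    "this subject's classification to the target class. Rank the options ",
    "from most to least preferable, weighing how effective and how ",
    "feasible each is (fewer and smaller adjustments are easier). ",
    "Return one line per option in the form\n",
    "RANK <rank>: OPTION <number>: <one-sentence plain-language summary>\n"
  )
}

rank_candidates <- function(req) {
  n_edges <- vapply(req$diffs, nrow, integer(1))
  total_nd <- vapply(req$diffs, function(d) sum(d$norm_delta), numeric(1))
  # invalid candidates always rank below valid ones
  order(!req$validity, n_edges, total_nd)
}

step_text <- function(req, l) {
  d <- req$diffs[[l]]
  if (!nrow(d)) return("No change required: already at the target class.")
  phr <- paste0(ifelse(d$delta > 0, "increase", "decrease"),
                " the connectivity between ",
                sub("--", " and ", req$edge_names[d$feature], fixed = TRUE),
                " from ", formatC(d$before, digits = 3, format = "f"),
                " to ", formatC(d$after, digits = 3, format = "f"))
  paste0(paste(phr, collapse = "; "), ".")
}

#' Template-based explanation report
#'
#' Deterministic offline rendering: one step per candidate, ranked by
#' fewest changed edges, then smallest total MAD-normalized change
#' (valid candidates always ahead of invalid ones) — a fixed
#' operationalization of "effectiveness and feasibility". Wording comes
#' from fixed templates.
#'
#' @param req An [explanation_request()].
#' @return Object of class `explanation_report` with `summary`, `steps`
#'   (data frame: `rank`, `candidate`, `n_edges`, `total_norm_change`,
#'   `valid`, `text`), and `provenance = "template"`. Every report ends
#'   with a research-use disclaimer.
#' @export
template_explanation <- function(req) {
  stopifnot(inherits(req, "explanation_request"))
  ord <- rank_candidates(req)
  steps <- data.frame(
    rank = seq_along(ord), candidate = ord,
    n_edges = vapply(req$diffs, nrow, integer(1))[ord],
    total_norm_change = vapply(req$diffs, function(d) sum(d$norm_delta),
                               numeric(1))[ord],
    valid = req$validity[ord],
    text = vapply(ord, function(l) step_text(req, l), character(1))
  )
  summary <- paste0(
    "Ranked counterfactual interventions (most preferable first):\n",
    paste0(sprintf("%d. [candidate %d%s] %s", steps$rank, steps$candidate,
                   ifelse(steps$valid, "", ", did not reach target"),
                   steps$text),
           collapse = "\n"),
    "\n\nFor research use only: these model-derived adjustments are ",
    "exploratory and are not clinical recommendations.")
  structure(list(summary = summary, steps = steps, provenance = "template"),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(x$summary, "\n", sep = "")
  cat("(provenance: ", x$provenance, ")\n", sep = "")
  invisible(x)
}

mock_explanation_provider <- function(prompt) {
  # echoes a well-formed ranking derived from the option order in the prompt
  n <- length(gregexpr("OPTION [0-9]+:", prompt)[[1]])
  paste0("RANK ", seq_len(n), ": OPTION ", seq_len(n),
         ": Adjust the listed connections toward the stated values.",
         collapse = "\n")
}

#' Provider-backed explanation report
#'
#' Sends the explanation prompt to a text-generation provider and parses
#' `RANK n: OPTION k: text` lines into ranked steps. On a malformed
#' response the verbatim text is kept in the summary and the template
#' ranking is attached with a warning; on provider failure the full
#' template report is returned with a notice. A report is therefore
#' always produced.
#'
#' @param req An [explanation_request()].
#' @param config A [provider_config()]; its `provider_fun` (or the
#'   built-in mock) answers the prompt.
#' @return An `explanation_report` with provenance `"llm"` or
#'   `"template"`.
#' @export
llm_explanation <- function(req, config = provider_config()) {
  prompt <- build_explanation_prompt(req)
  ask <- if (!is.null(config$provider_fun)) config$provider_fun else {
    mock_explanation_provider
  }
  resp <- tryCatch(ask(prompt), error = function(e) e)
  if (inherits(resp, "error")) {
    message("llm_explanation: provider failed (", conditionMessage(resp),
            "); falling back to the template report")
    return(template_explanation(req))
  }
  all_lines <- strsplit(resp, "\n", fixed = TRUE)[[1]]
  lines <- grep("^RANK [0-9]+: OPTION [0-9]+: .+", all_lines, value = TRUE)
  tmpl <- template_explanation(req)
  if (length(lines) != length(req$diffs)) {
    warning("llm_explanation: response did not follow the requested ",
            "structure; keeping verbatim text with template ranking")
    out <- tmpl
    out$summary <- paste0(resp, "\n\n[unparsed response; template ranking ",
                          "attached]\n", tmpl$summary)
    out$provenance <- "llm"
    return(out)
  }
  rk <- as.integer(sub("RANK ([0-9]+):.*", "\\1", lines))
  cand <- as.integer(sub(".*OPTION ([0-9]+):.*", "\\1", lines))
  txt <- sub("RANK [0-9]+: OPTION [0-9]+: ", "", lines)
  steps <- data.frame(
    rank = rk, candidate = cand,
    n_edges = vapply(req$diffs, nrow, integer(1))[cand],
    total_norm_change = vapply(req$diffs, function(d) sum(d$norm_delta),
                               numeric(1))[cand],
    valid = req$validity[cand], text = txt)
  steps <- steps[order(steps$rank), ]
  structure(list(summary = paste0(resp,
                   "\n\nFor research use only: these model-derived ",
                   "adjustments are exploratory and are not clinical ",
                   "recommendations."),
                 steps = steps, provenance = "llm"),
            class = "explanation_report")
}
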