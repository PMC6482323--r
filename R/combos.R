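# Drug/therapy combination extraction. A cue rule (one of a shipped set of
# 27 regular expressions such as "in combination with") is sought in each
# article; around each match a control phrase (the cue plus up to `window`
# tokens on each side) is built, flanked by left and right context nodes of
# up to `window` further tokens; distinct drug names found inside those
# regions form one combination record.

#' Load combination cue rules
#'
#' Reads a YAML list of `{rule_id, pattern, label, example}` entries,
#' checking that rule IDs are unique and that every pattern compiles. The
#' `example` field is a literal string matching the pattern, used by the
#' synthetic-corpus generator. The packaged default set has 27 rules.
#'
#' @param path Path to the YAML rule file; defaults to the packaged set.
#' @return Data frame with `rule_id` (integer), `pattern`, `label`,
#'   `example`.
#' @export
load_combination_rules <- function(path = system.file(
  "extdata", "combination_rules.yaml", package = "oncotext")) {
  raw <- yaml::read_yaml(path)
  rules <- data.frame(
    rule_id = vapply(raw, function(r) as.integer(r$rule_id), integer(1)),
    pattern = vapply(raw, function(r) as.character(r$pattern), character(1)),
    label = vapply(raw, function(r) as.character(r$label %||% ""),
                   character(1)),
    example = vapply(raw, function(r) as.character(r$example %||% ""),
                     character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rules$rule_id)) {
    stop("duplicate rule_id in combination rules", call. = FALSE)
  }
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({grepl(rules$pattern[i], "x", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("combination rule ", rules$rule_id[i],
                  " has a non-compiling pattern", call. = FALSE)
  }
  rules
}

#' Find cue-rule matches in an article
#'
#' Applies every rule pattern (case-insensitive) to the text, taking all
#' non-overlapping leftmost matches per rule; matches from different rules
#' may overlap. Each character match is mapped to the span of tokens it
#' intersects.
#'
#' @param tokens Token data frame from [tokenize()] for the text.
#' @param text The original text the tokens index into.
#' @param rules Rule data frame from [load_combination_rules()].
#' @return Data frame ordered by match start then rule_id: `rule_id`,
#'   `start`, `end` (character offsets), `first_token`, `last_token` (row
#'   indices into `tokens`), `match` (the matched surface).
#' @export
find_cue_matches <- function(tokens, text, rules) {
  out <- data.frame(rule_id = integer(), start = integer(), end = integer(),
                    first_token = integer(), last_token = integer(),
                    match = character(), stringsAsFactors = FALSE)
  if (!nzchar(text) || nrow(tokens) == 0L) return(out)
  res <- list()
  for (i in seq_len(nrow(rules))) {
    m <- gregexpr(rules$pattern[i], text, perl = TRUE,
                  ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m) - 1L
    en <- st + attr(m, "match.length")
    for (k in seq_along(st)) {
      covered <- which(tokens$start < en[k] & tokens$end > st[k])
      if (length(covered) == 0L) next
      res[[length(res) + 1L]] <- data.frame(
        rule_id = rules$rule_id[i], start = st[k], end = en[k],
        first_token = min(covered), last_token = max(covered),
        match = substring(text, st[k] + 1L, en[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(out)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$rule_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the context structure around a cue match
#'
#' The control phrase stored at the root is the matched cue span extended by
#' up to `window` tokens on each side; the left and right child nodes hold
#' up to `window` further tokens before and after the control phrase.
#' Truncation at document edges yields shorter (possibly empty) nodes. With
#' `extend_control = FALSE` the root holds the cue tokens only.
#'
#' @param tokens Token data frame from [tokenize()].
#' @param first_token,last_token Token-row indices of the cue match.
#' @param window Maximum node width in tokens (default 5).
#' @param extend_control Extend the control phrase by `window` tokens each
#'   side (default `TRUE`).
#' @return An object of class `context_tree`: list with integer token-index
#'   vectors `control`, `left`, `right`, plus `tokens` and the cue indices.
#' @export
build_context <- function(tokens, first_token, last_token, window = 5L,
                          extend_control = TRUE) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1L)
  n <- nrow(tokens)
  if (first_token < 1L || last_token > n || first_token > last_token) {
    stop("match span lies outside the document", call. = FALSE)
  }
  window <- as.integer(window)
  ext <- if (extend_control) window else 0L
  c_lo <- max(1L, first_token - ext)
  c_hi <- min(n, last_token + ext)
  l_lo <- max(1L, c_lo - window)
  r_hi <- min(n, c_hi + window)
  structure(list(
    control = seq.int(c_lo, c_hi),
    left = if (l_lo < c_lo) seq.int(l_lo, c_lo - 1L) else integer(),
    right = if (r_hi > c_hi) seq.int(c_hi + 1L, r_hi) else integer(),
    cue = c(first_token, last_token),
    window = window,
    tokens = tokens
  ), class = "context_tree")
}

#' @export
print.context_tree <- function(x, ...) {
  phr <- function(idx) paste(x$tokens$token[idx], collapse = " ")
  cat("<context_tree>\n")
  cat("  left   :", phr(x$left), "\n")
  cat("  control:", phr(x$control), "\n")
  cat("  right  :", phr(x$right), "\n")
  invisible(x)
}

# character span [lo, hi) covered by a set of token indices
.region_bounds <- function(tree) {
  idx <- c(tree$left, tree$control, tree$right)
  c(min(tree$tokens$start[idx]), max(tree$tokens$end[idx]))
}

#' Extract a drug combination from one context
#'
#' Collects the distinct canonical drug names whose mention spans intersect
#' the control phrase or the left/right context nodes. If at least two
#' distinct names (after case-insensitive comparison) are found, one record
#' holding all of them is returned; otherwise nothing.
#'
#' @param tree A `context_tree` from [build_context()].
#' @param mentions Mention data frame for the article (columns `canonical`
#'   or `surface`, `start`, `end`).
#' @param article_id Article identifier recorded in the output.
#' @param rule_id Rule identifier recorded in the output.
#' @return Data frame with zero or one row: `article_id`, `rule_id`,
#'   `drugs` (list column, names sorted), `control_phrase`,
#'   `evidence_start`, `evidence_end`.
#' @export
extract_combinations <- function(tree, mentions, article_id = "",
                                 rule_id = NA_integer_) {
  stopifnot(inherits(tree, "context_tree"))
  empty <- data.frame(article_id = character(), rule_id = integer(),
                      control_phrase = character(),
                      evidence_start = integer(), evidence_end = integer(),
                      stringsAsFactors = FALSE)
  empty$drugs <- list()
  if (is.null(mentions) || nrow(mentions) == 0L) return(empty)
  if (is.null(mentions$canonical)) mentions$canonical <- mentions$surface
  idx <- c(tree$left, tree$control, tree$right)
  tok <- tree$tokens
  hit <- vapply(seq_len(nrow(mentions)), function(k) {
    any(tok$start[idx] < mentions$end[k] & tok$end[idx] > mentions$start[k])
  }, logical(1))
  names_hit <- mentions$canonical[hit][order(mentions$start[hit])]
  names_hit <- names_hit[!duplicated(tolower(names_hit))]
  if (length(names_hit) < 2L) return(empty)
  bounds <- .region_bounds(tree)
  ctrl <- paste(tok$token[tree$control], collapse = " ")
  out <- data.frame(article_id = article_id, rule_id = as.integer(rule_id),
                    control_phrase = ctrl,
                    evidence_start = bounds[1], evidence_end = bounds[2],
                    stringsAsFactors = FALSE)
  out$drugs <- list(sort(names_hit, method = "radix"))
  out
}

#' Extract combinations for a whole corpus
#'
#' Runs [find_cue_matches()], [build_context()] and
#' [extract_combinations()] over every article, then deduplicates identical
#' (article, drug set) pairs keeping the lowest rule_id. Ordering is
#' deterministic: article_id, rule_id, then the sorted drug string.
#'
#' @param x A [corpus()].
#' @param rules Rule data frame from [load_combination_rules()].
#' @param mentions_by_article Named list (by article_id) of mention data
#'   frames, or one data frame with an `article_id` column.
#' @param window Context window size in tokens (default 5).
#' @param extend_control Passed to [build_context()].
#' @return Data frame of combination records: `article_id`, `rule_id`,
#'   `drugs` (list column), `control_phrase`, `evidence_start`,
#'   `evidence_end`.
#' @export
extract_all <- function(x, rules, mentions_by_article, window = 5L,
                        extend_control = TRUE) {
  stopifnot(inherits(x, "corpus"))
  if (is.data.frame(mentions_by_article)) {
    mentions_by_article <- split(mentions_by_article,
                                 mentions_by_article$article_id)
  }
  texts <- article_text(x)
  recs <- list()
  for (i in seq_len(nrow(x))) {
    men <- mentions_by_article[[x$article_id[i]]]
    if (is.null(men) || nrow(men) == 0L) next
    toks <- tokenize(texts[i])
    matches <- find_cue_matches(toks, texts[i], rules)
    for (k in seq_len(nrow(matches))) {
      tree <- build_context(toks, matches$first_token[k],
                            matches$last_token[k], window = window,
                            extend_control = extend_control)
      r <- extract_combinations(tree, men, article_id = x$article_id[i],
                                rule_id = matches$rule_id[k])
      if (nrow(r) > 0L) recs[[length(recs) + 1L]] <- r
    }
  }
  if (length(recs) == 0L) {
    out <- data.frame(article_id = character(), rule_id = integer(),
                      control_phrase = character(),
                      evidence_start = integer(), evidence_end = integer(),
                      stringsAsFactors = FALSE)
    out$drugs <- list()
    return(out[c("article_id", "rule_id", "drugs", "control_phrase",
                 "evidence_start", "evidence_end")])
  }
  out <- do.call(rbind, recs)
  key <- tolower(.drug_key(out$drugs))
  ord <- order(out$article_id, key, out$rule_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out <- out[!duplicated(paste0(out$article_id, "\r", tolower(.drug_key(out$drugs)))), ,
             drop = FALSE]
  ord2 <- order(out$article_id, out$rule_id, .drug_key(out$drugs),
                method = "radix")
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  out[c("article_id", "rule_id", "drugs", "control_phrase",
        "evidence_start", "evidence_end")]
}
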