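# Drug/therapy named-entity recognition: a per-token probabilistic tagger
# (maximum-entropy family, fitted as ridge-penalised logistic regression)
# plus a regular-expression false-positive filter and exact lexicon
# matching. Mentions carry 0-based half-open character offsets into the
# article's analysis text (title + " " + abstract, see article_text()).

.word_shape <- function(tokens) {
  s <- gsub("[A-Z]", "X", tokens)
  s <- gsub("[a-z]", "x", s)
  gsub("[0-9]", "d", s)
}

# Sparse feature strings for each token in a sequence: identity, lowercase
# form, 2-4 character prefixes/suffixes, word shape (full and run-collapsed)
# and the lowercase forms of neighbours within distance 2.
.token_features <- function(tokens) {
  n <- length(tokens)
  low <- tolower(tokens)
  shape <- .word_shape(tokens)
  shape2 <- gsub("(.)\\1+", "\\1", shape)
  pad <- function(off) {
    idx <- seq_len(n) + off
    out <- ifelse(idx < 1L, "<s>", ifelse(idx > n, "</s>", low[pmin(pmax(idx, 1L), n)]))
    out
  }
  p1 <- pad(-1L); p2 <- pad(-2L); n1 <- pad(1L); n2 <- pad(2L)
  nc <- nchar(tokens)
  feats <- vector("list", n)
  for (i in seq_len(n)) {
    f <- c(paste0("w=", tokens[i]),
           paste0("lw=", low[i]),
           paste0("sh=", shape[i]),
           paste0("sh2=", shape2[i]),
           paste0("p1=", p1[i]), paste0("p2=", p2[i]),
           paste0("n1=", n1[i]), paste0("n2=", n2[i]))
    for (k in 2:4) {
      if (nc[i] >= k) {
        f <- c(f, paste0("pre", k, "=", substr(low[i], 1L, k)),
               paste0("suf", k, "=", substr(low[i], nc[i] - k + 1L, nc[i])))
      }
    }
    if (grepl("[0-9]", tokens[i])) f <- c(f, "hasdigit")
    if (grepl("-", tokens[i], fixed = TRUE)) f <- c(f, "hasdash")
    if (grepl("^[A-Z]", tokens[i])) f <- c(f, "initcap")
    feats[[i]] <- f
  }
  feats
}

.feature_matrix <- function(feats, vocab) {
  idx <- lapply(feats, function(f) {
    j <- match(f, vocab)
    j[!is.na(j)]
  })
  i <- rep.int(seq_along(idx), lengths(idx))
  Matrix::sparseMatrix(i = i, j = unlist(idx, use.names = FALSE), x = 1,
                       dims = c(length(feats), length(vocab)))
}

#' Train the drug-name tagger
#'
#' Fits a per-token probabilistic classifier of the maximum-entropy family
#' (log-linear; here a ridge-penalised logistic regression) over sparse
#' token features: token identity, lowercase form, 2-4 character prefixes
#' and suffixes, word shape, and neighbouring tokens within distance 2.
#' Training tokens are labelled positive when their span overlaps an
#' annotated entity span.
#'
#' @param x A [corpus()].
#' @param entities Stand-off annotations: data frame with columns
#'   `article_id`, `start`, `end` (0-based half-open character offsets into
#'   [article_text()]) and optionally `surface`.
#' @param seed Integer seed (the fit itself is deterministic; the seed is
#'   recorded for provenance).
#' @param lambda Ridge penalty (default `1e-3`).
#' @return An object of class `drug_tagger`.
#' @export
train_drug_tagger <- function(x, entities, seed = 1L, lambda = 1e-3) {
  stopifnot(inherits(x, "corpus"),
            all(c("article_id", "start", "end") %in% names(entities)))
  if (nrow(entities) == 0L) {
    stop("no annotated entities in training data", call. = FALSE)
  }
  texts <- article_text(x)
  feats <- list(); y <- logical()
  for (i in seq_len(nrow(x))) {
    toks <- tokenize(texts[i])
    if (nrow(toks) == 0L) next
    ent <- entities[entities$article_id == x$article_id[i], , drop = FALSE]
    pos <- rep(FALSE, nrow(toks))
    for (k in seq_len(nrow(ent))) {
      pos <- pos | (toks$start < ent$end[k] & toks$end > ent$start[k])
    }
    feats <- c(feats, .token_features(toks$token))
    y <- c(y, pos)
  }
  if (!any(y)) stop("no annotated entities in training data", call. = FALSE)
  vocab <- unique(unlist(feats, use.names = FALSE))
  X <- .feature_matrix(feats, vocab)
  set.seed(seed)
  fit <- glmnet::glmnet(X, factor(as.integer(y), levels = c("0", "1")),
                        family = "binomial", alpha = 0,
                        lambda = c(0.1, 0.01, lambda),
                        standardize = FALSE)
  structure(list(fit = fit, lambda = lambda, vocabulary = vocab,
                 seed = seed, n_train_tokens = length(y),
                 n_positive = sum(y)),
            class = "drug_tagger")
}

#' @export
print.drug_tagger <- function(x, ...) {
  cat(sprintf(paste0("<drug_tagger> maximum-entropy token classifier\n",
                     "  %d training tokens (%d entity tokens), ",
                     "%d features, ridge lambda = %g\n"),
              x$n_train_tokens, x$n_positive, length(x$vocabulary),
              x$lambda))
  invisible(x)
}

#' Tag drug mentions in text
#'
#' Scores each token with the trained tagger; maximal contiguous runs of
#' positive tokens (probability >= 0.5) become one mention with offsets into
#' the original text. Features unseen in training are ignored.
#'
#' @param model A `drug_tagger` from [train_drug_tagger()].
#' @param text A single character string.
#' @return Data frame of mentions: `surface`, `start`, `end`, `score` (mean
#'   token probability) and `source = "model"`.
#' @export
tag_drugs <- function(model, text) {
  stopifnot(inherits(model, "drug_tagger"))
  empty <- data.frame(surface = character(), start = integer(),
                      end = integer(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE)
  toks <- tokenize(text)
  if (nrow(toks) == 0L) return(empty)
  feats <- .token_features(toks$token)
  X <- .feature_matrix(feats, model$vocabulary)
  p <- as.numeric(stats::predict(model$fit, X, s = model$lambda,
                                 type = "response"))
  pos <- p >= 0.5
  if (!any(pos)) return(empty)
  r <- rle(pos)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  data.frame(
    surface = vapply(runs, function(k) substring(
      text, toks$start[starts[k]] + 1L, toks$end[stops[k]]), character(1)),
    start = toks$start[starts[runs]],
    end = toks$end[stops[runs]],
    score = vapply(runs, function(k) mean(p[starts[k]:stops[k]]),
                   numeric(1)),
    source = "model", stringsAsFactors = FALSE
  )
}

#' Load false-positive filter rules
#'
#' Reads a YAML list of `{rule_id, pattern, description}` entries and checks
#' that every pattern compiles. The packaged default set targets the
#' non-drug shapes the tagger tends to pick up: comparison expressions such
#' as "P≤0.001" (a letter-initial token with a comparison operator and a
#' numeric tail), percentages, units, and generic therapy words like
#' "inhibitor".
#'
#' @param path Path to the YAML rule file; defaults to the packaged set.
#' @return Data frame with `rule_id`, `pattern`, `description`.
#' @export
load_filter_rules <- function(path = system.file("extdata",
                                                 "filter_rules.yaml",
                                                 package = "oncotext")) {
  raw <- yaml::read_yaml(path)
  rules <- data.frame(
    rule_id = vapply(raw, function(r) as.character(r$rule_id), character(1)),
    pattern = vapply(raw, function(r) as.character(r$pattern), character(1)),
    description = vapply(raw, function(r)
      as.character(r$description %||% ""), character(1)),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(rules))) {
    ok <- tryCatch({grepl(rules$pattern[i], "x", perl = TRUE); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("filter rule '", rules$rule_id[i],
                  "' has a non-compiling pattern: ", rules$pattern[i],
                  call. = FALSE)
  }
  rules
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove false-positive mentions
#'
#' Drops a mention if and only if any rule's pattern matches its full
#' surface string (patterns are implicitly anchored). Order is preserved and
#' filtering is idempotent; with an empty rule set the input is returned
#' unchanged.
#'
#' @param mentions Mention data frame (columns `surface`, `start`, `end`,
#'   ...).
#' @param rules Rule data frame from [load_filter_rules()] (or any data
#'   frame with a `pattern` column).
#' @return The retained mentions, same columns, original order.
#' @export
filter_false_positives <- function(mentions, rules) {
  if (is.null(mentions) || nrow(mentions) == 0L) return(mentions)
  if (is.null(rules) || nrow(rules) == 0L) return(mentions)
  drop <- rep(FALSE, nrow(mentions))
  for (pat in rules$pattern) {
    drop <- drop | grepl(paste0("^(?:", pat, ")$"), mentions$surface,
                         perl = TRUE)
  }
  out <- mentions[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find lexicon drug names in text
#'
#' Case-insensitive, token-boundary-anchored, longest-match search for the
#' lexicon's drug names: "carboplatin" does not match inside
#' "carboplatinum", and of two overlapping names ("interferon",
#' "interferon alfa") the longer wins.
#'
#' @param text A single character string.
#' @param lexicon Data frame with a `name` column (e.g. from
#'   [generate_lexicon()] or a drug-database table).
#' @return Data frame of mentions: `surface` (as in the text), `canonical`
#'   (the lexicon spelling), `start`, `end`, `source = "lexicon"`.
#' @export
harvest_lexicon_mentions <- function(text, lexicon) {
  stopifnot(is.character(text), length(text) == 1L, "name" %in% names(lexicon))
  empty <- data.frame(surface = character(), canonical = character(),
                      start = integer(), end = integer(),
                      source = character(), stringsAsFactors = FALSE)
  if (!nzchar(text) || nrow(lexicon) == 0L) return(empty)
  cand <- list()
  for (nm in unique(lexicon$name)) {
    esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", nm)
    pat <- paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m) - 1L
    en <- st + attr(m, "match.length")
    cand[[length(cand) + 1L]] <- data.frame(
      canonical = nm, start = st, end = en, stringsAsFactors = FALSE)
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  # longest match wins among overlaps; then leftmost
  cand <- cand[order(cand$start, -(cand$end - cand$start), method = "radix"), ,
               drop = FALSE]
  keep <- logical(nrow(cand))
  last_end <- -1L
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- cand$end[i]
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(surface = substring(text, cand$start + 1L, cand$end),
             canonical = cand$canonical,
             start = cand$start, end = cand$end,
             source = "lexicon", stringsAsFactors = FALSE)
}

#' Union model and lexicon mentions
#'
#' Combines tagger output and lexicon matches, deduplicating by exact span;
#' on an exact span tie the model-sourced mention is preferred.
#'
#' @param model_mentions,lexicon_mentions Mention data frames (as from
#'   [tag_drugs()] and [harvest_lexicon_mentions()]).
#' @return One mention data frame ordered by `start`; a `canonical` column
#'   is present (the surface form where no lexicon spelling applies).
#' @export
combine_mentions <- function(model_mentions, lexicon_mentions) {
  norm <- function(m) {
    if (is.null(m) || nrow(m) == 0L) {
      return(data.frame(surface = character(), canonical = character(),
                        start = integer(), end = integer(),
                        source = character(), stringsAsFactors = FALSE))
    }
    if (is.null(m$canonical)) m$canonical <- m$surface
    m[c("surface", "canonical", "start", "end", "source")]
  }
  all <- rbind(norm(model_mentions), norm(lexicon_mentions))
  pref <- ifelse(all$source == "model", 0L, 1L)
  all <- all[order(all$start, all$end, pref, method = "radix"), , drop = FALSE]
  all <- all[!duplicated(all[c("start", "end")]), , drop = FALSE]
  rownames(all) <- NULL
  all
}
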