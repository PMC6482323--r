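# Corpus-level tagging and entity-level evaluation.

#' Tag drug mentions across a corpus
#'
#' Runs [tag_drugs()] on every article's analysis text and binds the
#' results with an `article_id` column.
#'
#' @param model A `drug_tagger`.
#' @param x A [corpus()].
#' @return Mention data frame: `article_id`, `surface`, `start`, `end`,
#'   `score`, `source`.
#' @export
tag_corpus <- function(model, x) {
  stopifnot(inherits(x, "corpus"))
  texts <- article_text(x)
  out <- lapply(seq_len(nrow(x)), function(i) {
    m <- tag_drugs(model, texts[i])
    if (nrow(m) == 0L) return(NULL)
    cbind(data.frame(article_id = x$article_id[i],
                     stringsAsFactors = FALSE), m)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(article_id = character(), surface = character(),
                      start = integer(), end = integer(), score = numeric(),
                      source = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Entity-level precision, recall and F-score
#'
#' Scores predicted mentions against gold stand-off annotations by exact
#' (article_id, start, end) span match.
#'
#' @param predicted,gold Data frames with columns `article_id`, `start`,
#'   `end`.
#' @return List with `precision`, `recall`, `f_score`, `tp`, `fp`, `fn`.
#' @export
entity_metrics <- function(predicted, gold) {
  key <- function(d) paste(d$article_id, d$start, d$end, sep = ":")
  pk <- unique(key(predicted))
  gk <- unique(key(gold))
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  m <- eval_metrics(tp, fp, fn, 0L)
  list(precision = m$precision, recall = m$recall, f_score = m$f_score,
       tp = tp, fp = fp, fn = fn)
}
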