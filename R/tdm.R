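# Word n-gram term-document matrix (trigrams by default), the feature space
# of the outcome classifier.

.ngrams <- function(tokens, n) {
  k <- length(tokens) - n + 1L
  if (k < 1L) return(character())
  vapply(seq_len(k), function(i) paste(tokens[i:(i + n - 1L)], collapse = " "),
         character(1))
}

#' Build a term-document matrix of word n-grams
#'
#' Terms are contiguous word n-grams (trigrams by default) joined by a
#' single space; counts are raw occurrence counts; the vocabulary is ordered
#' by first occurrence across documents. Documents shorter than `n` tokens
#' contribute an all-zero row.
#'
#' @param docs List of character vectors (tokenized documents, typically
#'   from [preprocess()]).
#' @param n Gram size, a positive integer (default 3).
#' @param doc_ids Optional character vector of document identifiers; default
#'   `"doc1"`, `"doc2"`, ...
#' @return An object of class `tdm`: a list with `counts` (a sparse
#'   documents-by-terms [Matrix::dgCMatrix-class]), `vocabulary` and
#'   `doc_ids`.
#' @examples
#' build_tdm(list(c("a", "b", "c", "d")), n = 3)
#' @export
build_tdm <- function(docs, n = 3L, doc_ids = NULL) {
  stopifnot(is.list(docs))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1L) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.null(doc_ids)) doc_ids <- paste0("doc", seq_along(docs))
  stopifnot(length(doc_ids) == length(docs), !anyDuplicated(doc_ids))

  grams <- lapply(docs, .ngrams, n = n)
  vocab <- unique(unlist(grams, use.names = FALSE))
  if (is.null(vocab)) vocab <- character()

  i <- integer(); j <- integer(); x <- integer()
  for (d in seq_along(grams)) {
    if (length(grams[[d]]) == 0L) next
    tab <- table(grams[[d]])
    i <- c(i, rep.int(d, length(tab)))
    j <- c(j, match(names(tab), vocab))
    x <- c(x, as.integer(tab))
  }
  counts <- Matrix::sparseMatrix(
    i = i, j = j, x = x,
    dims = c(length(docs), length(vocab)),
    dimnames = list(doc_ids, vocab)
  )
  structure(list(counts = counts, vocabulary = vocab, doc_ids = doc_ids),
            class = "tdm")
}

#' @export
print.tdm <- function(x, ...) {
  cat(sprintf("Term-document matrix: %d documents x %d terms (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), Matrix::nnzero(x$counts)))
  invisible(x)
}

#' @export
dim.tdm <- function(x) dim(x$counts)
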