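# Tokenization and sentence segmentation shared by the classifier, the
# tagger and the combination extractor. Offsets are 0-based half-open
# character positions into the original string, so substr(text, start + 1,
# end) always recovers the surface form.

# One token is either
#   * a word: letter-initial, internal hyphens kept ("ABT-737" is one token),
#     optionally continued by a comparison operator and a numeric tail so
#     statistics expressions such as "P<=0.001" or "IC50=20" survive as a
#     single token for the false-positive filter;
#   * a number, with internal decimal points ("2.5");
#   * any other single non-space character (punctuation token).
.token_pattern <- paste0(
  "[[:alpha:]](?:[[:alnum:]]|-(?=[[:alnum:]]))*",
  "(?:(?:<=|>=|[<>=≤≥])[0-9]+(?:\\.[0-9]+)*)?",
  "|[0-9]+(?:\\.[0-9]+)*",
  "|\\S"
)

#' Tokenize text with character offsets
#'
#' Splits raw text into tokens, keeping drug-style names with internal
#' hyphens ("ABT-737"), decimal numbers ("2.5") and comparison expressions
#' ("P≤0.001", "IC50=20") as single tokens, and emitting every other
#' non-space character as a punctuation token. This is the tokenization used
#' for entity tagging and context windows; the classifier pipeline in
#' [preprocess()] additionally drops punctuation tokens.
#'
#' @param text A single character string.
#' @return A data frame with columns `token`, `start`, `end`; offsets are
#'   0-based, half-open, so `substr(text, start + 1, end)` equals `token`.
#' @examples
#' tokenize("ABT-737 with paclitaxel (P<=0.001).")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(token = substring(text, start + 1L, end),
             start = start, end = end, stringsAsFactors = FALSE)
}

# Abbreviations that must not end a sentence.
.abbreviations <- c(
  "al", "approx", "ca", "cf", "dr", "e.g", "eg", "et", "etc", "fig", "figs",
  "i.e", "ie", "inc", "jr", "mr", "mrs", "ms", "no", "prof", "resp", "sp",
  "spp", "st", "vs", "viz"
)

#' Segment text into sentences
#'
#' Splits on sentence-final punctuation (`.`, `!`, `?`) followed by
#' whitespace, guarding decimal numbers (no whitespace after the point) and
#' a list of common abbreviations ("et al.", "e.g.", "Fig.", single
#' initials). Spans are contiguous and cover the whole text.
#'
#' @param text A single character string.
#' @return A data frame with columns `start`, `end` (0-based half-open) and
#'   `sentence` (the span text, trailing whitespace included).
#' @examples
#' segment_sentences("Dose was 2.5 mg daily. No toxicity was seen.")
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer(),
                      sentence = character(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[.!?]+(\\s+|$)", text, perl = TRUE)[[1]]
  bounds <- integer()
  if (m[1] != -1L) {
    for (i in seq_along(m)) {
      pos <- as.integer(m[i])                 # 1-based position of punctuation
      len <- attr(m, "match.length")[i]
      # word immediately before the punctuation
      before <- sub(".*?([[:alnum:].-]*)$", "\\1", substr(text, 1L, pos - 1L))
      w <- tolower(sub("\\.$", "", before))
      if (w %in% .abbreviations) next
      if (grepl("^[A-Za-z]$", before)) next   # single-letter initial
      bounds <- c(bounds, pos - 1L + len)     # 0-based end incl. whitespace
    }
  }
  n <- nchar(text)
  if (length(bounds) == 0L || bounds[length(bounds)] < n) {
    bounds <- c(bounds, n)
  }
  start <- c(0L, bounds[-length(bounds)])
  keep <- start < bounds
  start <- start[keep]
  end <- as.integer(bounds[keep])
  data.frame(start = start, end = end,
             sentence = substring(text, start + 1L, end),
             stringsAsFactors = FALSE)
}
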