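# Classifier-side preprocessing: case folding, character normalization,
# stopword removal and stemming, in that order.

.greek_map <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ε" = "epsilon", "κ" = "kappa",
  "λ" = "lambda", "μ" = "mu", "µ" = "mu", "π" = "pi",
  "σ" = "sigma", "τ" = "tau", "ω" = "omega",
  "Α" = "alpha", "Β" = "beta", "Γ" = "gamma",
  "Δ" = "delta", "Κ" = "kappa", "Λ" = "lambda",
  "Σ" = "sigma", "Ω" = "omega"
)

#' Normalize text characters
#'
#' Deterministic character-level spelling normalization: spells out common
#' Greek letters (so "TNF-α" becomes "TNF-alpha"), unifies typographic
#' hyphens/dashes and the Unicode minus to ASCII `-`, straightens curly
#' quotes, expands the fi/fl ligatures and converts non-breaking spaces to
#' plain spaces. No edit-distance spelling correction is attempted.
#'
#' @param x Character vector.
#' @return Character vector of the same length.
#' @export
normalize_chars <- function(x) {
  stopifnot(is.character(x))
  for (i in seq_along(.greek_map)) {
    x <- gsub(names(.greek_map)[i], .greek_map[[i]], x, fixed = TRUE)
  }
  x <- gsub("[‐‑‒–—―−]", "-", x, perl = TRUE)
  x <- gsub("[‘’‛]", "'", x, perl = TRUE)
  x <- gsub("[“”]", "\"", x, perl = TRUE)
  x <- gsub("ﬁ", "fi", x, fixed = TRUE)
  x <- gsub("ﬂ", "fl", x, fixed = TRUE)
  gsub(" ", " ", x, fixed = TRUE)
}

#' Default English stopword list
#'
#' Reads the packaged plain-text stopword list (one token per line). Users
#' may supply their own list to [preprocess()].
#'
#' @param path Path to a stopword file; defaults to the packaged list.
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function(path = system.file("extdata", "stopwords_en.txt",
                                                 package = "oncotext")) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Preprocess text into classifier tokens
#'
#' The classification pipeline: tokenize, lowercase, normalize characters,
#' drop punctuation-only tokens, remove stopwords, then Porter-stem purely
#' alphabetic tokens. Tokens containing digits or hyphens (drug names like
#' "abt-737") are kept unstemmed.
#'
#' @param text A single character string (may be empty).
#' @param stopwords Character vector of stopwords; `character()` disables
#'   removal.
#' @param stem Apply Porter stemming (default `TRUE`).
#' @return Character vector of processed tokens (possibly empty).
#' @examples
#' preprocess("Paclitaxel inhibits the tumors")
#' @export
preprocess <- function(text, stopwords = default_stopwords(), stem = TRUE) {
  toks <- tokenize(text)$token
  if (length(toks) == 0L) return(character())
  toks <- normalize_chars(tolower(toks))
  toks <- toks[grepl("^[a-z0-9]", toks)]           # drop punctuation tokens
  toks <- toks[!toks %in% stopwords]
  if (stem) {
    alpha <- grepl("^[a-z]+$", toks)
    toks[alpha] <- porter_stem(toks[alpha])
  }
  toks
}
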