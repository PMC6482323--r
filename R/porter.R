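# Porter's suffix-stripping stemmer (the classic 1980 algorithm), used by
# the classifier's preprocessing pipeline. Implemented here because the
# algorithm is small, fully specified, and must be deterministic across
# platforms. Operates on lowercase ASCII words; anything else is returned
# unchanged.

# TRUE for consonant positions. y is a consonant at word start or after a
# vowel, a vowel after a consonant.
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# measure m = number of vowel->consonant transitions in [C](VC)^m[V]
.porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  cons <- .porter_cons(strsplit(stem, "", fixed = TRUE)[[1]])
  runs <- rle(cons)$values
  sum(runs[-1] & !runs[-length(runs)])
}

.has_vowel <- function(stem) {
  if (!nzchar(stem)) return(FALSE)
  any(!.porter_cons(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.ends_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[n] != chars[n - 1L]) return(FALSE)
  all(.porter_cons(chars)[c(n - 1L, n)])
}

# *o condition: stem ends consonant-vowel-consonant, final consonant not w/x/y
.ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  cons <- .porter_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.chop <- function(word, k) substr(word, 1L, nchar(word) - k)

# Replace the longest matching suffix from `rules` (named list suffix ->
# replacement) when `cond(stem)` holds. Per the algorithm, the longest
# matching suffix decides; if its condition fails, the word is unchanged.
.rule_step <- function(word, rules, cond) {
  sufs <- names(rules)
  sufs <- sufs[order(nchar(sufs), decreasing = TRUE)]
  for (suf in sufs) {
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      if (cond(stem)) return(paste0(stem, rules[[suf]]))
      return(word)
    }
  }
  word
}

.porter1 <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # Step 1a
  if (endsWith(word, "sses")) {
    word <- paste0(.chop(word, 4L), "ss")
  } else if (endsWith(word, "ies")) {
    word <- paste0(.chop(word, 3L), "i")
  } else if (!endsWith(word, "ss") && endsWith(word, "s")) {
    word <- .chop(word, 1L)
  }

  # Step 1b
  stripped <- FALSE
  if (endsWith(word, "eed")) {
    stem <- .chop(word, 3L)
    if (.porter_m(stem) > 0L) word <- paste0(stem, "ee")
  } else if (endsWith(word, "ed") && .has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L)
    stripped <- TRUE
  } else if (endsWith(word, "ing") && .has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L)
    stripped <- TRUE
  }
  if (stripped) {
    if (endsWith(word, "at") || endsWith(word, "bl") || endsWith(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.ends_double_cons(word) &&
               !substr(word, nchar(word), nchar(word)) %in% c("l", "s", "z")) {
      word <- .chop(word, 1L)
    } else if (.porter_m(word) == 1L && .ends_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # Step 1c
  if (endsWith(word, "y") && .has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  # Step 2
  word <- .rule_step(word, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"
  ), function(stem) .porter_m(stem) > 0L)

  # Step 3
  word <- .rule_step(word, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""
  ), function(stem) .porter_m(stem) > 0L)

  # Step 4 ("ion" only after s/t)
  sufs4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ion", "ism",
             "ate", "iti", "ous", "ive", "ize", "ent", "ant", "al", "er",
             "ic", "ou")
  sufs4 <- sufs4[order(nchar(sufs4), decreasing = TRUE)]
  for (suf in sufs4) {
    if (endsWith(word, suf)) {
      stem <- .chop(word, nchar(suf))
      ok <- .porter_m(stem) > 1L
      if (suf == "ion") {
        ok <- ok && (endsWith(stem, "s") || endsWith(stem, "t"))
      }
      if (ok) word <- stem
      break
    }
  }

  # Step 5a
  if (endsWith(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) word <- stem
  }

  # Step 5b
  if (.porter_m(word) > 1L && .ends_double_cons(word) && endsWith(word, "l")) {
    word <- .chop(word, 1L)
  }

  word
}

#' Porter stem words
#'
#' Applies the Porter suffix-stripping algorithm to each element. Words that
#' are not purely lowercase `a`-`z` (after no case folding here — callers
#' lowercase first) or that are two characters or shorter are returned
#' unchanged.
#'
#' @param words Character vector.
#' @return Character vector of stems, same length.
#' @examples
#' porter_stem(c("inhibits", "tumors", "relational", "paclitaxel"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, function(w) {
    if (is.na(w) || !grepl("^[a-z]+$", w)) w else .porter1(w)
  }, character(1), USE.NAMES = FALSE)
}
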