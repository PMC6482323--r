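# Corpus container and Medline/PubMed XML I/O. Only PMID, ArticleTitle and
# AbstractText are consumed; that is all the downstream pipeline uses.

#' Construct a corpus of articles
#'
#' @param articles Data frame with columns `article_id`, `title`, `abstract`
#'   and optionally `language`.
#' @param source Free-text provenance label stored as an attribute.
#' @return An object of class `corpus` (a data frame).
#' @export
corpus <- function(articles, source = "unknown") {
  stopifnot(is.data.frame(articles),
            all(c("article_id", "title", "abstract") %in% names(articles)))
  articles$article_id <- as.character(articles$article_id)
  articles$title <- as.character(articles$title)
  articles$abstract <- as.character(articles$abstract)
  if (is.null(articles$language)) articles$language <- NA_character_
  if (any(!nzchar(articles$article_id)) || anyNA(articles$article_id)) {
    stop("every article needs a non-empty article_id", call. = FALSE)
  }
  if (anyDuplicated(articles$article_id)) {
    stop("duplicate article_id in corpus: ",
         paste(unique(articles$article_id[duplicated(articles$article_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(articles$title)) || anyNA(articles$title)) {
    stop("every article needs a non-empty title", call. = FALSE)
  }
  articles$abstract[is.na(articles$abstract)] <- ""
  rownames(articles) <- NULL
  structure(articles[c("article_id", "title", "abstract", "language")],
            source = source, class = c("corpus", "data.frame"))
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d articles (source: %s)\n",
              nrow(x), attr(x, "source")))
  if (nrow(x) > 0L) {
    shown <- utils::head(x, 5L)
    for (i in seq_len(nrow(shown))) {
      cat(sprintf("  [%s] %s\n", shown$article_id[i],
                  substr(shown$title[i], 1L, 60L)))
    }
    if (nrow(x) > 5L) cat(sprintf("  ... and %d more\n", nrow(x) - 5L))
  }
  invisible(x)
}

# Full analysis text of each article: title + " " + abstract. All stand-off
# character offsets (entities, mentions, combination evidence) index into
# this string.
#' Analysis text of articles
#'
#' Title and abstract joined by a single space; the string into which all
#' stand-off character offsets point.
#'
#' @param x A `corpus` or a data frame with `title` and `abstract` columns.
#' @return Character vector, one element per article.
#' @export
article_text <- function(x) {
  ab <- ifelse(is.na(x$abstract) | !nzchar(x$abstract), "", x$abstract)
  trimws(paste(x$title, ab), which = "right")
}

#' Read a Medline/PubMed XML article set
#'
#' Accepts a `PubmedArticleSet` or `ArticleSet` root (or one bare
#' `PubmedArticle`). One article per `PubmedArticle` record; the abstract is
#' the concatenation of all `AbstractText` sections in document order,
#' joined by single spaces; a record without an `Abstract` element gets an
#' empty abstract. Records without a PMID are skipped with a warning.
#'
#' @param path Path to the XML file.
#' @return A [corpus()].
#' @export
read_medline_xml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path, encoding = "UTF-8"),
                  error = function(e) {
                    stop("malformed XML in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  root <- xml2::xml_name(doc)
  if (!root %in% c("PubmedArticleSet", "ArticleSet", "PubmedArticle")) {
    stop("unexpected XML root <", root,
         ">; expected PubmedArticleSet, ArticleSet or PubmedArticle",
         call. = FALSE)
  }
  nodes <- if (root == "PubmedArticle") list(doc) else
    xml2::xml_find_all(doc, ".//PubmedArticle")
  recs <- lapply(nodes, function(node) {
    pmid <- xml2::xml_text(
      xml2::xml_find_first(node, ".//MedlineCitation/PMID | ./PMID"))
    title <- xml2::xml_text(
      xml2::xml_find_first(node, ".//Article/ArticleTitle | .//ArticleTitle"))
    abst <- xml2::xml_text(
      xml2::xml_find_all(node, ".//Abstract/AbstractText"))
    lang <- xml2::xml_text(
      xml2::xml_find_first(node, ".//Article/Language | .//Language"))
    list(article_id = pmid, title = title,
         abstract = paste(abst, collapse = " "),
         language = if (is.na(lang)) NA_character_ else lang)
  })
  has_pmid <- vapply(recs, function(r) !is.na(r$article_id) &&
                       nzchar(r$article_id), logical(1))
  if (any(!has_pmid)) {
    warning(sum(!has_pmid), " record(s) without PMID skipped", call. = FALSE)
    recs <- recs[has_pmid]
  }
  df <- data.frame(
    article_id = vapply(recs, `[[`, character(1), "article_id"),
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    language = vapply(recs, `[[`, character(1), "language"),
    stringsAsFactors = FALSE
  )
  corpus(df, source = path)
}

#' Write a corpus as Medline/PubMed XML
#'
#' Emits a minimal `PubmedArticleSet` (PMID, ArticleTitle, AbstractText,
#' Language) that [read_medline_xml()] reads back. Output is deterministic.
#'
#' @param x A [corpus()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_medline_xml <- function(x, path) {
  stopifnot(inherits(x, "corpus"))
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(x))) {
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", x$article_id[i])
    a <- xml2::xml_add_child(cit, "Article")
    xml2::xml_add_child(a, "ArticleTitle", x$title[i])
    if (nzchar(x$abstract[i])) {
      ab <- xml2::xml_add_child(a, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", x$abstract[i])
    }
    if (!is.na(x$language[i])) {
      xml2::xml_add_child(a, "Language", x$language[i])
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a typed tab-separated table
#'
#' Reads a TSV with a header row and validates it against a column schema.
#' Supported types: `"character"`, `"numeric"`, `"integer"` and `"percent"`
#' (numeric, validated to lie in \[0, 100\]).
#'
#' @param path Path to the TSV file.
#' @param schema Named character vector mapping required column names to
#'   types, e.g. `c(similarity = "percent", human_gene_id = "character")`.
#'   Columns not named in the schema are kept as character.
#' @return A data frame with typed columns.
#' @export
read_typed_tsv <- function(path, schema) {
  stopifnot(is.character(schema), !is.null(names(schema)))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = NULL, fileEncoding = "UTF-8")
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "percent")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      if (anyNA(v) && !anyNA(df[[col]])) {
        stop("column '", col, "' contains non-numeric values", call. = FALSE)
      }
      if (type == "percent" && any(v < 0 | v > 100, na.rm = TRUE)) {
        stop("column '", col, "' has percent values outside [0, 100]",
             call. = FALSE)
      }
      df[[col]] <- v
    } else if (type == "integer") {
      df[[col]] <- as.integer(df[[col]])
    }
  }
  df
}

# Canonical serialized form of a drug set: C-locale lexicographic sort,
# joined by "|".
.drug_key <- function(drugs) {
  vapply(drugs, function(d) paste(sort(unique(d), method = "radix"),
                                  collapse = "|"), character(1))
}

#' Write combination records to a TSV file
#'
#' Columns: `article_id`, `rule_id`, `drugs` (names sorted lexicographically
#' and joined by `|`) and `control_phrase`. Rows are ordered by article_id,
#' then rule_id, then the drug string, so repeated runs give byte-identical
#' files.
#'
#' @param records A data frame of combination records as returned by
#'   [extract_all()]: columns `article_id`, `rule_id`, `drugs` (list column
#'   of character vectors) and `control_phrase`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(records, path) {
  if (is.null(records) || nrow(records) == 0L) {
    writeLines("article_id\trule_id\tdrugs\tcontrol_phrase", path,
               useBytes = TRUE)
    return(invisible(path))
  }
  stopifnot(all(c("article_id", "rule_id", "drugs", "control_phrase")
                %in% names(records)))
  key <- .drug_key(records$drugs)
  ord <- order(records$article_id, records$rule_id, key, method = "radix")
  out <- data.frame(article_id = records$article_id[ord],
                    rule_id = records$rule_id[ord],
                    drugs = key[ord],
                    control_phrase = records$control_phrase[ord],
                    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("article_id\trule_id\tdrugs\tcontrol_phrase",
               sprintf("%s\t%d\t%s\t%s", out$article_id,
                       as.integer(out$rule_id), out$drugs,
                       out$control_phrase)),
             con, useBytes = TRUE)
  invisible(path)
}

#' Read combination records back from a results TSV
#'
#' Inverse of [write_results()]: the `drugs` column is split on `|` into a
#' list column.
#'
#' @param path Path to a results TSV written by [write_results()].
#' @return Data frame with `article_id`, `rule_id`, `drugs` (list column)
#'   and `control_phrase`.
#' @export
read_results <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  df$rule_id <- as.integer(df$rule_id)
  df$drugs <- strsplit(df$drugs, "|", fixed = TRUE)
  df
}
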