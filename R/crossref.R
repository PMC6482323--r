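# Cross-referencing extracted drug names against offline drug-database
# tables (DrugBank/PubChem/ChemSpider-style name lists). Names that match
# no table are flagged as new drugs/substances.

# matching key: lowercase, character-normalized, hyphens/spaces unified
.canon_drug <- function(x) {
  x <- normalize_chars(tolower(x))
  x <- gsub("[-[:space:]]+", " ", x)
  trimws(x)
}

#' Load a drug-database table
#'
#' @param path TSV with columns `name`, `db_id`, `synonyms` (pipe-separated;
#'   empty or `-` for none).
#' @param db_name Label for the table (e.g. `"drugbank"`).
#' @return An object of class `drug_table`.
#' @export
read_drug_table <- function(path, db_name) {
  df <- read_typed_tsv(path, c(name = "character", db_id = "character"))
  if (is.null(df$synonyms)) df$synonyms <- ""
  drug_table(df, db_name)
}

#' Construct a drug-database table
#'
#' @param entries Data frame with `name`, `db_id` and optionally `synonyms`
#'   (pipe-separated string).
#' @param db_name Label for the table.
#' @return An object of class `drug_table`.
#' @export
drug_table <- function(entries, db_name) {
  stopifnot(all(c("name", "db_id") %in% names(entries)),
            is.character(db_name), length(db_name) == 1L)
  if (anyDuplicated(entries$db_id)) {
    stop("duplicate db_id in drug table '", db_name, "'", call. = FALSE)
  }
  if (is.null(entries$synonyms)) entries$synonyms <- ""
  structure(list(db_name = db_name,
                 entries = entries[c("name", "db_id", "synonyms")]),
            class = "drug_table")
}

#' @export
print.drug_table <- function(x, ...) {
  cat(sprintf("<drug_table> %s: %d entries\n", x$db_name, nrow(x$entries)))
  invisible(x)
}

# key -> db_id lookup for one table (names + synonyms; first key wins)
.table_keys <- function(tab) {
  e <- tab$entries
  syns <- strsplit(ifelse(is.na(e$synonyms), "", e$synonyms), "|",
                   fixed = TRUE)
  keys <- c(.canon_drug(e$name),
            .canon_drug(unlist(syns, use.names = FALSE)))
  ids <- c(e$db_id, rep(e$db_id, lengths(syns)))
  keep <- nzchar(keys) & keys != "-"
  keys <- keys[keep]; ids <- ids[keep]
  ids[!duplicated(keys)] -> ids2
  names(ids2) <- keys[!duplicated(keys)]
  ids2
}

#' Cross-reference drug names against database tables
#'
#' Each input name is matched case-insensitively (after character
#' normalization and hyphen/space unification) against the names and
#' synonyms of the tables in priority order: the first table listed that
#' contains the name wins. Names found in no table go to `unmapped`; mapped
#' and unmapped always partition the input set.
#'
#' @param drugs Character vector of drug names (deduplicated
#'   case-insensitively).
#' @param tables Ordered list of `drug_table` objects, highest priority
#'   first.
#' @return An object of class `crossref_result`: list with `mapped` (data
#'   frame `drug`, `db_name`, `db_id`) and `unmapped` (character vector).
#' @export
cross_reference <- function(drugs, tables) {
  stopifnot(is.character(drugs), is.list(tables),
            all(vapply(tables, inherits, logical(1), "drug_table")))
  drugs <- drugs[!duplicated(.canon_drug(drugs))]
  keymaps <- lapply(tables, .table_keys)
  db_names <- vapply(tables, `[[`, character(1), "db_name")
  keys <- .canon_drug(drugs)
  db <- rep(NA_character_, length(drugs))
  id <- rep(NA_character_, length(drugs))
  for (t in seq_along(tables)) {
    open <- is.na(db)
    hit <- match(keys[open], names(keymaps[[t]]))
    found <- which(open)[!is.na(hit)]
    db[found] <- db_names[t]
    id[found] <- keymaps[[t]][hit[!is.na(hit)]]
  }
  mapped <- data.frame(drug = drugs[!is.na(db)], db_name = db[!is.na(db)],
                       db_id = id[!is.na(db)], stringsAsFactors = FALSE)
  structure(list(mapped = mapped, unmapped = drugs[is.na(db)],
                 db_names = db_names),
            class = "crossref_result")
}

#' @export
print.crossref_result <- function(x, ...) {
  cat(sprintf("<crossref_result> %d mapped, %d unmapped\n",
              nrow(x$mapped), length(x$unmapped)))
  invisible(x)
}

#' Summarize a cross-reference result
#'
#' Per-source counts of mapped names plus a `"new"` category for unmapped
#' names; the counts always sum to the number of distinct input names.
#'
#' @param result A `crossref_result` from [cross_reference()].
#' @return Named integer vector: one entry per database (in priority order)
#'   plus `new`.
#' @export
summarize_crossref <- function(result) {
  stopifnot(inherits(result, "crossref_result"))
  counts <- vapply(result$db_names, function(d)
    sum(result$mapped$db_name == d), integer(1))
  c(counts, new = length(result$unmapped))
}
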