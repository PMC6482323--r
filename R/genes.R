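# Candidate-gene selection and PubMed query construction. Candidates are
# human-dog ortholog pairs whose human member carries somatic mutations in
# tumors and whose protein similarity is at least a threshold (default 75%,
# inclusive).

#' Select candidate cancer genes
#'
#' Cross-references a human-dog ortholog table with a somatic-mutation gene
#' catalog: a candidate is an ortholog pair whose human gene maps (via the
#' Entrez-to-Ensembl `id_map`) to a catalog gene and whose similarity is at
#' least `threshold` (inclusive). When several ortholog rows share one human
#' gene, the row with the highest similarity is kept (ties broken by
#' lexicographically smallest dog gene ID). Catalog entries with no id_map
#' entry are excluded and reported via a message.
#'
#' @param orthologs Data frame with columns `human_gene_id`, `dog_gene_id`,
#'   `similarity` (percent in \[0, 100\]) and optionally `description`.
#' @param somatic_catalog Data frame with columns `symbol`, `entrez_id`.
#' @param id_map Data frame with columns `entrez_id`, `human_gene_id`.
#' @param threshold Minimum percent similarity, inclusive (default 75).
#' @return Data frame of candidates, sorted by `symbol`: columns `symbol`,
#'   `human_gene_id`, `dog_gene_id`, `similarity`, `entrez_id`, and
#'   `description` if present. The number of unmapped catalog genes is
#'   attached as attribute `n_unmapped`.
#' @export
select_candidates <- function(orthologs, somatic_catalog, id_map,
                              threshold = 75) {
  stopifnot(all(c("human_gene_id", "dog_gene_id", "similarity")
                %in% names(orthologs)),
            all(c("symbol", "entrez_id") %in% names(somatic_catalog)),
            all(c("entrez_id", "human_gene_id") %in% names(id_map)),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 100)
  if (any(orthologs$similarity < 0 | orthologs$similarity > 100,
          na.rm = TRUE)) {
    stop("ortholog similarity outside [0, 100]", call. = FALSE)
  }

  # one row per human gene: highest similarity, tie-break on dog_gene_id
  ord <- order(orthologs$human_gene_id, -orthologs$similarity,
               orthologs$dog_gene_id, method = "radix")
  orth <- orthologs[ord, , drop = FALSE]
  orth <- orth[!duplicated(orth$human_gene_id), , drop = FALSE]

  mapped_idx <- match(as.character(somatic_catalog$entrez_id),
                      as.character(id_map$entrez_id))
  n_unmapped <- sum(is.na(mapped_idx))
  if (n_unmapped > 0L) {
    message(n_unmapped, " somatic-catalog gene(s) had no ID mapping and ",
            "were excluded")
  }
  cat_mapped <- somatic_catalog[!is.na(mapped_idx), , drop = FALSE]
  cat_mapped$human_gene_id <- id_map$human_gene_id[mapped_idx[!is.na(mapped_idx)]]

  hit <- match(cat_mapped$human_gene_id, orth$human_gene_id)
  keep <- !is.na(hit)
  cand <- data.frame(
    symbol = as.character(cat_mapped$symbol[keep]),
    human_gene_id = cat_mapped$human_gene_id[keep],
    dog_gene_id = orth$dog_gene_id[hit[keep]],
    similarity = orth$similarity[hit[keep]],
    entrez_id = as.character(cat_mapped$entrez_id[keep]),
    stringsAsFactors = FALSE
  )
  if (!is.null(orth$description)) {
    cand$description <- orth$description[hit[keep]]
  }
  cand <- cand[cand$similarity >= threshold, , drop = FALSE]
  cand <- cand[order(cand$symbol, method = "radix"), , drop = FALSE]
  rownames(cand) <- NULL
  attr(cand, "n_unmapped") <- n_unmapped
  cand
}

#' Build per-gene query term lists
#'
#' For each gene symbol, assembles the ordered list of PubMed query terms:
#' the gene's synonyms in source order (the gene_info placeholder `"-"` is
#' dropped; duplicates differing only in case are kept once), then
#' `"HGNC: <id>"` (with a space), `"MIM:<id>"` (no space),
#' `"Ensembl: <human id>"` (with a space) and `"Ensembl:<dog id>"` (no
#' space). Missing ID sources simply omit those terms. The spacing quirks
#' are preserved verbatim from the upstream source conventions.
#'
#' @param gene_info Data frame with columns `symbol` and `synonyms`
#'   (pipe-separated string, `"-"` meaning none).
#' @param hgnc_ids,omim_ids,ensembl_human,ensembl_dog Named character
#'   vectors mapping symbol to the respective identifier (may be `NULL` or
#'   lack entries).
#' @return Named list: symbol -> ordered character vector of query terms.
#' @export
build_synonym_table <- function(gene_info, hgnc_ids = NULL, omim_ids = NULL,
                                ensembl_human = NULL, ensembl_dog = NULL) {
  stopifnot(all(c("symbol", "synonyms") %in% names(gene_info)))
  out <- vector("list", nrow(gene_info))
  names(out) <- gene_info$symbol
  for (i in seq_len(nrow(gene_info))) {
    sym <- gene_info$symbol[i]
    syns <- strsplit(gene_info$synonyms[i], "|", fixed = TRUE)[[1]]
    syns <- syns[nzchar(syns) & syns != "-"]
    syns <- syns[!duplicated(tolower(syns))]
    terms <- syns
    if (!is.null(hgnc_ids) && sym %in% names(hgnc_ids)) {
      terms <- c(terms, paste0("HGNC: ", hgnc_ids[[sym]]))
    }
    if (!is.null(omim_ids) && sym %in% names(omim_ids)) {
      terms <- c(terms, paste0("MIM:", omim_ids[[sym]]))
    }
    if (!is.null(ensembl_human) && sym %in% names(ensembl_human)) {
      terms <- c(terms, paste0("Ensembl: ", ensembl_human[[sym]]))
    }
    if (!is.null(ensembl_dog) && sym %in% names(ensembl_dog)) {
      terms <- c(terms, paste0("Ensembl:", ensembl_dog[[sym]]))
    }
    out[[i]] <- terms
  }
  out
}

#' Build a left-nested PubMed boolean OR query
#'
#' For terms `t1 ... tn` the query is built by folding from the left:
#' `(t1)`, then `((t1) OR t2)`, `(((t1) OR t2) OR t3)` and so on, matching
#' the query syntax submitted to PubMed.
#'
#' @param terms Character vector of at least one query term.
#' @return A single query string.
#' @examples
#' build_pubmed_query(c("TP53"))
#' build_pubmed_query(c("A", "B"))
#' @export
build_pubmed_query <- function(terms) {
  if (!is.character(terms) || length(terms) < 1L || anyNA(terms)) {
    stop("`terms` must be a character vector with at least one term",
         call. = FALSE)
  }
  q <- paste0("(", terms[1], ")")
  for (t in terms[-1]) q <- paste0("(", q, " OR ", t, ")")
  q
}

#' Write one query per gene
#'
#' Emits `symbol<TAB>query` lines for a synonym table, using
#' [build_pubmed_query()] per gene. Genes with no terms are skipped with a
#' warning.
#'
#' @param synonym_table Named list from [build_synonym_table()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_queries <- function(synonym_table, path) {
  empty <- vapply(synonym_table, function(x) length(x) == 0L, logical(1))
  if (any(empty)) {
    warning("skipping gene(s) with no query terms: ",
            paste(names(synonym_table)[empty], collapse = ", "),
            call. = FALSE)
  }
  tab <- synonym_table[!empty]
  lines <- vapply(names(tab), function(sym) {
    paste0(sym, "\t", build_pubmed_query(tab[[sym]]))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
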