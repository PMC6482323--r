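# Independent oracles and small fixture builders shared across tests.

# Brute-force candidate selection: explicit double loop over the somatic
# catalog and the ortholog table, independent of select_candidates().
brute_candidates <- function(orthologs, somatic, id_map, threshold) {
  o_human <- orthologs$human_gene_id; o_dog <- orthologs$dog_gene_id
  o_sim <- orthologs$similarity
  m_entrez <- id_map$entrez_id; m_human <- id_map$human_gene_id
  hits <- list()
  for (i in seq_len(nrow(somatic))) {
    ens <- NA_character_
    for (j in seq_along(m_entrez)) {
      if (m_entrez[j] == somatic$entrez_id[i]) {
        ens <- m_human[j]
        break
      }
    }
    if (is.na(ens)) next
    best <- 0L
    for (j in seq_along(o_human)) {
      if (o_human[j] != ens) next
      if (best == 0L || o_sim[j] > o_sim[best] ||
          (o_sim[j] == o_sim[best] && o_dog[j] < o_dog[best])) {
        best <- j
      }
    }
    if (best == 0L || o_sim[best] < threshold) next
    hits[[length(hits) + 1L]] <- data.frame(
      symbol = somatic$symbol[i],
      human_gene_id = ens,
      dog_gene_id = o_dog[best],
      similarity = o_sim[best],
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) {
    return(data.frame(symbol = character(), human_gene_id = character(),
                      dog_gene_id = character(), similarity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$symbol, method = "radix"), , drop = FALSE]
}

# random candidate-selection problem for the oracle-equivalence tests;
# similarities include values pinned exactly at the 75.0 boundary
random_gene_problem <- function(n_pairs = 1000L, n_catalog = 50L) {
  human <- sprintf("ENSG%011d", sample.int(n_pairs * 2L, n_pairs))
  sim <- round(stats::runif(n_pairs, 40, 100), 1)
  sim[sample.int(n_pairs, 20L)] <- 75.0
  orth <- data.frame(
    human_gene_id = human,
    dog_gene_id = sprintf("ENSCAFG%011d", sample.int(n_pairs * 2L, n_pairs)),
    similarity = sim, stringsAsFactors = FALSE)
  pick <- sample(unique(human), n_catalog)
  som <- data.frame(symbol = sprintf("GENE%03d", seq_along(pick)),
                    entrez_id = as.character(seq_along(pick) + 1000L),
                    stringsAsFactors = FALSE)
  idm <- data.frame(entrez_id = som$entrez_id, human_gene_id = pick,
                    stringsAsFactors = FALSE)
  list(orthologs = orth, somatic = som, id_map = idm)
}

# Brute-force combination oracle: every pair of distinct drug names whose
# mentions co-occur within (2 * window) tokens of a cue match. Independent
# of the context-tree construction in extract_all().
brute_combo_pairs <- function(corp, rules, mentions_by_article, window) {
  out <- character()
  texts <- article_text(corp)
  for (i in seq_len(nrow(corp))) {
    men <- mentions_by_article[[corp$article_id[i]]]
    if (is.null(men) || nrow(men) == 0L) next
    if (is.null(men$canonical)) men$canonical <- men$surface
    toks <- tokenize(texts[i])
    for (r in seq_len(nrow(rules))) {
      m <- gregexpr(rules$pattern[r], texts[i], perl = TRUE,
                    ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        st <- as.integer(m[k]) - 1L
        en <- st + attr(m, "match.length")[k]
        cue_tok <- which(toks$start < en & toks$end > st)
        if (length(cue_tok) == 0L) next
        lo <- max(1L, min(cue_tok) - 2L * window)
        hi <- min(nrow(toks), max(cue_tok) + 2L * window)
        rs <- toks$start[lo]; re <- toks$end[hi]
        inside <- men$canonical[men$start < re & men$end > rs]
        inside <- inside[!duplicated(tolower(inside))]
        if (length(inside) < 2L) next
        for (a in seq_len(length(inside) - 1L)) {
          for (b in seq.int(a + 1L, length(inside))) {
            pair <- sort(c(inside[a], inside[b]), method = "radix")
            out <- c(out, paste(corp$article_id[i], pair[1], pair[2],
                                sep = "\r"))
          }
        }
      }
    }
  }
  unique(out)
}

# explode extract_all() records into the same article/pair keys
records_to_pairs <- function(recs) {
  out <- character()
  for (i in seq_len(nrow(recs))) {
    d <- recs$drugs[[i]]
    for (a in seq_len(length(d) - 1L)) {
      for (b in seq.int(a + 1L, length(d))) {
        out <- c(out, paste(recs$article_id[i], d[a], d[b], sep = "\r"))
      }
    }
  }
  unique(out)
}

record_keys <- function(article_id, drugs) {
  paste(article_id,
        vapply(drugs, function(d) paste(sort(tolower(d), method = "radix"),
                                        collapse = "|"), character(1)))
}

# lexicon-based mentions for every article of a corpus, as a named list
mentions_for_corpus <- function(corp, lexicon) {
  texts <- article_text(corp)
  out <- lapply(texts, harvest_lexicon_mentions, lexicon = lexicon)
  names(out) <- corp$article_id
  out
}

tiny_corpus <- function(ids, titles, abstracts) {
  corpus(data.frame(article_id = ids, title = titles, abstract = abstracts,
                    stringsAsFactors = FALSE), source = "test")
}

# subset a corpus by row index, keeping the corpus class
corpus_slice <- function(x, idx) {
  corpus(as.data.frame(x)[idx, , drop = FALSE], source = attr(x, "source"))
}
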