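# Synthetic labeled corpora: Medline-style abstracts with planted drug
# mentions, combination cue phrases, success/failure outcome language and
# statistics-expression distractors, plus full ground truth, so every
# pipeline stage is testable without any download. Abstracts are template
# sentences, not realistic prose; see the methods vignette for what that
# does and does not exercise.

.sim_titles <- c(
  "A phase two study of systemic therapy in advanced carcinoma.",
  "Clinical evaluation of targeted agents in metastatic disease.",
  "A randomized trial of single agent therapy in solid tumors.",
  "Prospective assessment of novel regimens in refractory cancer."
)

.sim_fillers <- c(
  "The study enrolled forty two patients with advanced solid tumors.",
  "Median age at enrollment was sixty one years.",
  "Baseline characteristics were balanced between the study arms.",
  "All participants provided written informed consent before screening.",
  "The primary endpoint was assessed after six cycles.",
  "Laboratory values were monitored at every visit.",
  "Imaging studies were scheduled every eight weeks.",
  "The protocol was approved by the institutional review board.",
  "Eligibility required adequate hepatic and renal function.",
  "Patients were stratified by stage and performance status."
)

.sim_drug_sentences <- c(
  "Patients received {drug} at the standard dose.",
  "Treatment with {drug} was generally well tolerated.",
  "The pharmacokinetics of {drug} were evaluated in all cohorts.",
  "Dose escalation of {drug} proceeded without dose limiting toxicity.",
  "Serum levels of {drug} were measured at steady state.",
  "A daily schedule of {drug} was maintained throughout therapy."
)

.sim_outcome_frames <- c(
  "Overall {cue} in the treated cohort.",
  "By the final analysis {cue} across all arms.",
  "Investigators noted that {cue} during extended observation.",
  "The trial showed that {cue} at interim review."
)

.sim_combo_frames <- c(
  "Patients in the experimental arm received {A} {cue} {B} every three weeks.",
  "The regimen of {A} {cue} {B} was evaluated in the second cohort.",
  "Responses were assessed for {A} {cue} {B} in eligible patients."
)

.sim_distractors <- c(
  "The observed difference reached P≤0.001 in the adjusted model.",
  "Response criteria required IC50=20 in the cell viability assays.",
  "The hazard estimate was HR>=1.2 for the comparator group."
)

.success_cues <- c(
  "complete tumor remission achieved",
  "marked tumor regression observed",
  "durable objective response noted",
  "significant survival benefit observed",
  "favorable clinical outcome reported",
  "prolonged disease stabilization achieved",
  "improved overall survival reported",
  "sustained therapeutic benefit noted",
  "notable symptom relief achieved",
  "excellent disease control reported",
  "strong antitumor activity observed",
  "encouraging remission rates reported"
)

.failure_cues <- c(
  "rapid disease progression occurred",
  "severe toxicity forced discontinuation",
  "poor therapeutic outcome reported",
  "negligible antitumor effect observed",
  "early treatment resistance developed",
  "unacceptable adverse events occurred",
  "minimal clinical improvement noted",
  "disappointing response rates reported",
  "frequent early relapse occurred",
  "worsening symptom burden documented",
  "inferior survival outcomes reported",
  "progressive disease was confirmed"
)

.name_syllables <- c(
  "ba", "be", "bi", "bo", "da", "de", "do", "fa", "fe", "fi", "ga", "ge",
  "go", "ka", "ke", "ki", "la", "le", "lo", "ma", "me", "mi", "na", "ne",
  "no", "pa", "pe", "po", "ra", "re", "ro", "sa", "se", "so", "ta", "te",
  "to", "va", "ve", "vo", "za", "ze", "zo"
)
.name_suffixes <- c(
  "tinib", "ciclib", "parib", "zomib", "fenib", "sertib", "lisib", "mab",
  "zumab", "ximab", "taxel", "platin", "rubicin", "mycin", "citabine",
  "arabine", "poside", "otecan", "navir", "stat", "feron", "cept"
)

.sim_anchors <- c("ABT-737", "paclitaxel", "imatinib")

#' Configuration for the synthetic-corpus generator
#'
#' Defaults are the generator's study conditions: a 17% treatment-failure
#' rate (the share of failure-reporting articles seen in the literature
#' analysis this pipeline emulates), a drug lexicon of 1308 names split
#' 656/451/104/97 across drugbank/pubchem/chemspider/new, fully disjoint
#' success and failure cue vocabularies (`vocab_separation = 1`), and a
#' planted combination in 30% of articles.
#'
#' @param n_articles Number of articles (positive integer).
#' @param failure_rate Fraction of articles labelled treatment failure
#'   (default 0.17).
#' @param combo_rate Fraction of articles containing one planted drug
#'   combination (default 0.3).
#' @param lexicon_size Number of drug names in the generated lexicon
#'   (default 1308).
#' @param vocab_separation In \[0, 1\]: 1 means success and failure articles
#'   draw outcome cues strictly from their own vocabularies; 0 means cues
#'   carry no class signal (default 1).
#' @param seed Integer seed; every corpus is byte-reproducible from it.
#' @param source_split Numeric vector of length 4 (drugbank, pubchem,
#'   chemspider, new): either proportions or absolute counts summing to
#'   `lexicon_size`. Defaults to the 656/451/104/97 proportions.
#' @param distractor_rate Fraction of articles carrying a statistics
#'   expression such as "P≤0.001" to exercise the false-positive filter
#'   (default 0.3).
#' @param drug_sentence_rate Chance that a non-mandatory sentence of a
#'   non-combination article mentions a drug (default 0.5).
#' @return An object of class `corpus_config`.
#' @export
corpus_config <- function(n_articles, failure_rate = 0.17, combo_rate = 0.3,
                          lexicon_size = 1308L, vocab_separation = 1,
                          seed = 1L,
                          source_split = c(drugbank = 656, pubchem = 451,
                                           chemspider = 104, new = 97),
                          distractor_rate = 0.3, drug_sentence_rate = 0.5) {
  stopifnot(is.numeric(n_articles), n_articles >= 1,
            failure_rate >= 0, failure_rate <= 1,
            combo_rate >= 0, combo_rate <= 1,
            vocab_separation >= 0, vocab_separation <= 1,
            distractor_rate >= 0, distractor_rate <= 1,
            lexicon_size >= 1, length(source_split) == 4L)
  if (lexicon_size < 2 && combo_rate > 0) {
    stop("combo_rate > 0 needs a lexicon of at least 2 names", call. = FALSE)
  }
  structure(list(n_articles = as.integer(n_articles),
                 failure_rate = failure_rate, combo_rate = combo_rate,
                 lexicon_size = as.integer(lexicon_size),
                 vocab_separation = vocab_separation, seed = as.integer(seed),
                 source_split = source_split,
                 distractor_rate = distractor_rate,
                 drug_sentence_rate = drug_sentence_rate),
            class = "corpus_config")
}

# largest-remainder apportionment of `total` into proportions `p`
.apportion <- function(p, total) {
  q <- p / sum(p) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic drug lexicon
#'
#' Pronounceable synthetic names (syllables plus drug-style suffixes such as
#' "-tinib", "-platin") together with three real anchor names (ABT-737,
#' paclitaxel, imatinib) so the worked examples run against generated
#' corpora. Each name is assigned to drugbank, pubchem, chemspider or "new"
#' per the configured split (counts, or proportions apportioned by largest
#' remainder). The anchors are drugbank entries; imatinib carries the
#' synonyms Gleevec and Glivec.
#'
#' @param config A [corpus_config()].
#' @return Data frame with `name`, `source_db`, `source_id`, `synonyms`.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  .with_seed(config$seed + 1L, {
    size <- config$lexicon_size
    names <- .sim_anchors[seq_len(min(length(.sim_anchors), size))]
    while (length(names) < size) {
      need <- size - length(names)
      cand <- paste0(sample(.name_syllables, need * 2L, replace = TRUE),
                     sample(.name_syllables, need * 2L, replace = TRUE),
                     sample(.name_suffixes, need * 2L, replace = TRUE))
      names <- unique(c(names, cand))[seq_len(min(size, length(unique(c(names, cand)))))]
    }
    split <- config$source_split
    counts <- if (isTRUE(all.equal(sum(split), size))) {
      as.integer(round(split))
    } else {
      .apportion(split, size)
    }
    src <- rep(c("drugbank", "pubchem", "chemspider", "new"), counts)
    # anchors stay in drugbank: assign sources to the shuffled non-anchor
    # names after pinning anchors to the front (drugbank block)
    anchors <- names[names %in% .sim_anchors]
    others <- sample(setdiff(names, anchors))
    ordered <- c(anchors, others)
    if (counts[1] < length(anchors)) {
      src[seq_along(anchors)] <- "drugbank"   # degenerate tiny lexicons
    }
    ids <- character(size)
    for (s in unique(src)) {
      pref <- c(drugbank = "DB", pubchem = "CID", chemspider = "CS",
                new = "NEW")[[s]]
      ids[src == s] <- sprintf("%s%05d", pref, seq_len(sum(src == s)))
    }
    syn <- ifelse(ordered == "imatinib", "Gleevec|Glivec", "")
    data.frame(name = ordered, source_db = src, source_id = ids,
               synonyms = syn, stringsAsFactors = FALSE)
  })
}

#' Drug-database tables from a generated lexicon
#'
#' Builds one [drug_table()] per external source (drugbank, pubchem,
#' chemspider) from the lexicon's planted split; "new" names belong to no
#' table, which is what makes them unmapped under [cross_reference()].
#'
#' @param lexicon Data frame from [generate_lexicon()].
#' @return Named list of `drug_table` objects in priority order.
#' @export
lexicon_to_tables <- function(lexicon) {
  out <- list()
  for (s in c("drugbank", "pubchem", "chemspider")) {
    e <- lexicon[lexicon$source_db == s,
                 c("name", "source_id", "synonyms"), drop = FALSE]
    names(e) <- c("name", "db_id", "synonyms")
    rownames(e) <- NULL
    out[[s]] <- drug_table(e, s)
  }
  out
}

# substitute {key} placeholders, returning 0-based spans of the values
.fill_template <- function(tmpl, values) {
  text <- tmpl
  spans <- list()
  repeat {
    m <- regexpr("\\{[A-Za-z]+\\}", text, perl = TRUE)
    if (m == -1L) break
    len <- attr(m, "match.length")
    key <- substr(text, m + 1L, m + len - 2L)
    val <- values[[key]]
    start <- as.integer(m) - 1L
    text <- paste0(substr(text, 1L, m - 1L), val,
                   substring(text, m + len))
    spans[[length(spans) + 1L]] <- list(key = key, start = start,
                                        end = start + nchar(val), value = val)
  }
  list(text = text, spans = spans)
}

#' Generate a synthetic labeled corpus with ground truth
#'
#' Emits a corpus of template-sentence abstracts with planted drug mentions,
#' treatment-outcome cue language, optional combination cue phrases (drawn
#' from the shipped combination rules, with two distinct drugs placed
#' directly around the cue, inside the five-word windows) and
#' statistics-expression distractors — plus the full ground truth. In
#' combination articles drugs occur only in the combination sentence, so
#' the planted set is exactly what a windowed extractor should recover.
#' Deterministic per seed; repeated runs write byte-identical files.
#'
#' @param config A [corpus_config()].
#' @param dir Optional output directory; when given, writes `corpus.xml`
#'   (Medline format), `labels.tsv`, `entities.tsv`, `combinations.tsv` and
#'   `lexicon.tsv` there.
#' @param rules Combination rules used for planting cues (default the
#'   packaged set).
#' @return Invisibly (visibly when `dir` is `NULL`) a list: `corpus`,
#'   `labels`, `entities`, `combinations` (list column `drugs`), `lexicon`,
#'   `config`.
#' @export
generate_corpus <- function(config, dir = NULL,
                            rules = load_combination_rules()) {
  stopifnot(inherits(config, "corpus_config"))
  lexicon <- generate_lexicon(config)
  plantable <- rules[nzchar(rules$example), , drop = FALSE]
  res <- .with_seed(config$seed, {
    n <- config$n_articles
    ids <- sprintf("%d", 100000L + seq_len(n))
    arts <- vector("list", n)
    labels <- integer(n)
    entities <- list()
    combos <- list()
    for (a in seq_len(n)) {
      label <- if (stats::runif(1) < config$failure_rate) 0L else 1L
      labels[a] <- label
      is_combo <- config$combo_rate > 0 &&
        stats::runif(1) < config$combo_rate
      n_sent <- sample(3:8, 1L)

      sents <- list()   # each: list(text, drug_spans = list of (start,end,name))
      add_sent <- function(text, spans = list()) {
        sents[[length(sents) + 1L]] <<- list(text = text, spans = spans)
      }

      # outcome sentence(s): cue from own class vocabulary with probability
      # (1 + separation) / 2, otherwise from the other class
      n_out <- sample(1:2, 1L)
      for (k in seq_len(n_out)) {
        own <- stats::runif(1) < (1 + config$vocab_separation) / 2
        pool <- if (xor(label == 1L, !own)) .success_cues else .failure_cues
        f <- .fill_template(sample(.sim_outcome_frames, 1L),
                            list(cue = sample(pool, 1L)))
        add_sent(f$text)
      }

      combo_drugs <- character()
      combo_rule <- NA_integer_
      combo_cue <- NA_character_
      if (is_combo) {
        combo_drugs <- sample(lexicon$name, 2L)
        ri <- sample(seq_len(nrow(plantable)), 1L)
        combo_rule <- plantable$rule_id[ri]
        combo_cue <- plantable$example[ri]
        f <- .fill_template(sample(.sim_combo_frames, 1L),
                            list(A = combo_drugs[1], cue = combo_cue,
                                 B = combo_drugs[2]))
        add_sent(f$text, Filter(function(s) s$key %in% c("A", "B"), f$spans))
      }

      if (stats::runif(1) < config$distractor_rate) {
        add_sent(sample(.sim_distractors, 1L))
      }

      while (length(sents) < n_sent) {
        if (!is_combo && stats::runif(1) < config$drug_sentence_rate) {
          d <- sample(lexicon$name, 1L)
          f <- .fill_template(sample(.sim_drug_sentences, 1L),
                              list(drug = d))
          add_sent(f$text, Filter(function(s) s$key == "drug", f$spans))
        } else {
          add_sent(sample(.sim_fillers, 1L))
        }
      }
      sents <- sents[sample.int(length(sents))]

      title <- sample(.sim_titles, 1L)
      offset <- nchar(title) + 1L   # the joining space in article_text()
      abstract <- character(length(sents))
      for (si in seq_along(sents)) {
        abstract[si] <- sents[[si]]$text
        for (sp in sents[[si]]$spans) {
          entities[[length(entities) + 1L]] <- data.frame(
            article_id = ids[a],
            start = offset + sp$start, end = offset + sp$end,
            surface = sp$value, stringsAsFactors = FALSE)
        }
        offset <- offset + nchar(abstract[si]) + 1L
      }
      if (is_combo) {
        cr <- data.frame(article_id = ids[a], rule_id = combo_rule,
                         cue = combo_cue, stringsAsFactors = FALSE)
        cr$drugs <- list(sort(combo_drugs, method = "radix"))
        combos[[length(combos) + 1L]] <- cr
      }
      arts[[a]] <- data.frame(article_id = ids[a], title = title,
                              abstract = paste(abstract, collapse = " "),
                              language = "eng", stringsAsFactors = FALSE)
    }
    list(
      corpus = corpus(do.call(rbind, arts), source = "synthetic"),
      labels = data.frame(article_id = ids, label = labels,
                          stringsAsFactors = FALSE),
      entities = if (length(entities) > 0L) do.call(rbind, entities) else
        data.frame(article_id = character(), start = integer(),
                   end = integer(), surface = character(),
                   stringsAsFactors = FALSE),
      combinations = if (length(combos) > 0L) do.call(rbind, combos) else {
        cd <- data.frame(article_id = character(), rule_id = integer(),
                         cue = character(), stringsAsFactors = FALSE)
        cd$drugs <- list(); cd
      },
      lexicon = lexicon,
      config = config
    )
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_medline_xml(res$corpus, file.path(dir, "corpus.xml"))
    .write_tsv <- function(df, path) {
      con <- file(path, open = "wb")
      on.exit(close(con))
      lines <- c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(unname(df), sep = "\t")))
      writeLines(lines, con, useBytes = TRUE)
    }
    .write_tsv(res$labels, file.path(dir, "labels.tsv"))
    .write_tsv(res$entities, file.path(dir, "entities.tsv"))
    comb <- res$combinations
    comb_flat <- data.frame(article_id = comb$article_id,
                            rule_id = comb$rule_id,
                            drugs = .drug_key(comb$drugs),
                            cue = comb$cue, stringsAsFactors = FALSE)
    .write_tsv(comb_flat, file.path(dir, "combinations.tsv"))
    .write_tsv(res$lexicon, file.path(dir, "lexicon.tsv"))
  }
  if (is.null(dir)) res else invisible(res)
}
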