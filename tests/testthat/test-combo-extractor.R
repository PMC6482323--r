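fig_corpus <- function() {
  corp <- read_medline_xml(system.file("extdata", "medline_sample.xml",
                                       package = "oncotext"))
  lex <- data.frame(name = c("ABT-737", "paclitaxel", "imatinib"),
                    stringsAsFactors = FALSE)
  list(corp = corp, lex = lex,
       mentions = mentions_for_corpus(corp, lex))
}

test_that("the worked combination example yields exactly one record", {
  fx <- fig_corpus()
  rules <- load_combination_rules()
  recs <- extract_all(fx$corp, rules, fx$mentions)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$article_id, "26000001")
  expect_equal(recs$rule_id, 9L)
  expect_equal(recs$drugs[[1]], c("ABT-737", "paclitaxel"))
})

test_that("cue matching reports all matches ordered by position then rule", {
  rules <- load_combination_rules()
  text <- "drug one in combination with drug two and later x plus y plus z"
  toks <- tokenize(text)
  m <- find_cue_matches(toks, text, rules)
  expect_equal(m$rule_id, c(9L, 2L, 2L))   # one combination cue, two plus
  expect_equal(m$start, sort(m$start))
  expect_equal(nrow(find_cue_matches(tokenize("no cues here"),
                                     "no cues here", rules)), 0L)
})

test_that("context windows truncate at document edges", {
  text <- paste(letters[1:20], collapse = " ")
  toks <- tokenize(text)
  # match at token 3: control extends only 2 tokens left, left node empty
  tree <- build_context(toks, 3L, 3L, window = 5L)
  expect_equal(tree$control, 1:8)
  expect_length(tree$left, 0L)
  expect_equal(length(tree$right), 5L)
  # mid-document: both contexts full
  tree2 <- build_context(toks, 11L, 11L, window = 2L)
  expect_equal(tree2$control, 9:13)
  expect_equal(tree2$left, 7:8)
  expect_equal(tree2$right, 14:15)
  # match on the final token: empty right context
  tree3 <- build_context(toks, 20L, 20L, window = 5L)
  expect_length(tree3$right, 0L)
  expect_error(build_context(toks, 25L, 25L), "outside")
  # cue-only control phrase option
  tree4 <- build_context(toks, 11L, 11L, window = 2L,
                         extend_control = FALSE)
  expect_equal(tree4$control, 11L)
  expect_equal(tree4$left, 9:10)
})

test_that("a single or repeated drug never forms a combination", {
  text <- "we used druga in combination with druga again today"
  toks <- tokenize(text)
  men <- data.frame(surface = c("druga", "druga"),
                    canonical = c("druga", "DrugA"),
                    start = c(8L, 34L), end = c(13L, 39L),
                    source = "lexicon", stringsAsFactors = FALSE)
  tree <- build_context(toks, 4L, 6L, window = 5L)
  expect_equal(nrow(extract_combinations(tree, men, "a1", 9L)), 0L)
  expect_equal(nrow(extract_combinations(tree, men[0, ], "a1", 9L)), 0L)
})

test_that("extraction equals ground truth and the brute-force oracle on synthetic combos", {
  g <- generate_corpus(corpus_config(n_articles = 120, combo_rate = 1,
                                     lexicon_size = 50, seed = 17))
  rules <- load_combination_rules()
  mentions <- mentions_for_corpus(g$corpus, g$lexicon)
  recs <- extract_all(g$corpus, rules, mentions, window = 5)
  expect_setequal(record_keys(recs$article_id, recs$drugs),
                  record_keys(g$combinations$article_id,
                              g$combinations$drugs))
  expect_setequal(records_to_pairs(recs),
                  brute_combo_pairs(g$corpus, rules, mentions, 5L))
})

test_that("output is invariant to rule-list order and window growth is monotone", {
  g <- generate_corpus(corpus_config(n_articles = 60, combo_rate = 1,
                                     lexicon_size = 30, seed = 19))
  rules <- load_combination_rules()
  mentions <- mentions_for_corpus(g$corpus, g$lexicon)
  base <- extract_all(g$corpus, rules, mentions, window = 5)
  set.seed(1)
  shuffled <- rules[sample.int(nrow(rules)), , drop = FALSE]
  again <- extract_all(g$corpus, shuffled, mentions, window = 5)
  expect_equal(record_keys(again$article_id, again$drugs),
               record_keys(base$article_id, base$drugs))
  found <- lapply(c(3, 5, 8), function(w) {
    r <- extract_all(g$corpus, rules, mentions, window = w)
    record_keys(r$article_id, r$drugs)
  })
  expect_true(all(found[[1]] %in% found[[2]]))
  expect_true(all(found[[2]] %in% found[[3]]))
})

test_that("no record names a drug outside the context regions", {
  set.seed(23)
  lex <- data.frame(name = c("aaa-drug", "bbb-drug", "ccc-drug"),
                    stringsAsFactors = FALSE)
  rules <- load_combination_rules()
  for (i in 1:25) {
    words <- sample(c("filler", "words", "assorted", "tokens", "various"),
                    40, replace = TRUE)
    # plant a cue and drugs at random positions
    pos <- sort(sample(40, 3))
    words[pos[1]] <- sample(lex$name, 1)
    words[pos[2]] <- "plus"
    words[pos[3]] <- sample(lex$name, 1)
    text <- paste(words, collapse = " ")
    corp <- tiny_corpus("a1", "T.", text)
    mentions <- mentions_for_corpus(corp, lex)
    recs <- extract_all(corp, rules, mentions, window = 5)
    for (k in seq_len(nrow(recs))) {
      txt <- article_text(corp)
      toks <- tokenize(txt)
      men <- mentions[["a1"]]
      for (d in recs$drugs[[k]]) {
        sp <- men[men$canonical == d, , drop = FALSE]
        # at least one mention of the drug lies inside the evidence span
        expect_true(any(sp$start < recs$evidence_end[k] &
                        sp$end > recs$evidence_start[k]))
      }
    }
  }
})

test_that("identical drug sets from two rules deduplicate to the lowest rule id", {
  text <- "druga combined with together with drugb here"
  corp <- tiny_corpus("a1", "T.", text)
  lex <- data.frame(name = c("druga", "drugb"), stringsAsFactors = FALSE)
  rules <- load_combination_rules()
  recs <- extract_all(corp, rules, mentions_for_corpus(corp, lex))
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$rule_id, 1L)   # "combined with" precedes "together with"
})
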