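test_that("false-positive filter drops comparison expressions, keeps drugs", {
  mentions <- data.frame(
    surface = c("P≤0.001", "IC50=20", "paclitaxel", "inhibitor", "HR>=1.2"),
    start = c(0L, 10L, 20L, 35L, 45L),
    end = c(7L, 17L, 30L, 44L, 51L),
    source = "model", stringsAsFactors = FALSE)
  rules <- load_filter_rules()
  kept <- filter_false_positives(mentions, rules)
  expect_equal(kept$surface, "paclitaxel")
  # idempotent
  expect_equal(filter_false_positives(kept, rules), kept)
  # identity under the empty rule set
  expect_equal(filter_false_positives(mentions, rules[0, ]), mentions)
  expect_equal(nrow(filter_false_positives(mentions[0, ], rules)), 0L)
})

test_that("packaged filter rules all compile and a bad pattern errors at load", {
  rules <- load_filter_rules()
  expect_gte(nrow(rules), 27L)
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("- rule_id: broken", "  pattern: '(['"), bad)
  expect_error(load_filter_rules(bad), "non-compiling")
})

test_that("lexicon harvesting is boundary-anchored, case-insensitive and longest-match", {
  lex <- data.frame(name = c("ABT-737", "paclitaxel", "carboplatin",
                             "interferon", "interferon alfa"),
                    stringsAsFactors = FALSE)
  m <- harvest_lexicon_mentions("ABT-737 with Paclitaxel works", lex)
  expect_equal(m$canonical, c("ABT-737", "paclitaxel"))
  expect_equal(m$surface, c("ABT-737", "Paclitaxel"))
  # no substring match inside a longer word
  expect_equal(nrow(harvest_lexicon_mentions(
    "carboplatinum dosing reviewed", lex)), 0L)
  # the longer of two overlapping names wins
  m2 <- harvest_lexicon_mentions("given interferon alfa daily", lex)
  expect_equal(m2$canonical, "interferon alfa")
  # offsets slice back to surfaces
  text <- "ABT-737 with Paclitaxel works"
  expect_identical(substring(text, m$start + 1L, m$end), m$surface)
})

test_that("tagger memorizes planted entities and is deterministic", {
  corp <- tiny_corpus(
    as.character(1:6),
    rep("A treatment note.", 6),
    c("patients received zelotinib at the standard dose",
      "treatment with zelotinib was well tolerated",
      "serum levels of madoparib were measured daily",
      "dose escalation of madoparib proceeded slowly",
      "baseline characteristics were balanced between arms",
      "imaging studies were scheduled every eight weeks"))
  texts <- article_text(corp)
  ent <- do.call(rbind, lapply(1:4, function(i) {
    drug <- if (i <= 2) "zelotinib" else "madoparib"
    st <- as.integer(regexpr(drug, texts[i], fixed = TRUE)) - 1L
    data.frame(article_id = corp$article_id[i], start = st,
               end = st + nchar(drug), surface = drug,
               stringsAsFactors = FALSE)
  }))
  model <- suppressWarnings(train_drug_tagger(corp, ent, seed = 2))
  probe <- "control mice were given zelotinib weekly"
  m1 <- tag_drugs(model, probe)
  expect_equal(m1$surface, "zelotinib")
  expect_identical(substring(probe, m1$start + 1L, m1$end), m1$surface)
  # determinism: retrain with the same data and seed
  model2 <- suppressWarnings(train_drug_tagger(corp, ent, seed = 2))
  expect_equal(tag_drugs(model2, probe), m1)
  # empty text and entity-free training both behave
  expect_equal(nrow(tag_drugs(model, "")), 0L)
  expect_error(train_drug_tagger(corp, ent[0, ], seed = 1), "no annotated")
})

test_that("two separated drug tokens yield two mentions", {
  corp <- tiny_corpus(
    as.character(1:4),
    rep("A note.", 4),
    c("first velotaxel then later bezoplatin was given",
      "velotaxel was administered on day one",
      "bezoplatin was administered on day two",
      "no study medication was administered here"))
  texts <- article_text(corp)
  ent <- do.call(rbind, lapply(1:3, function(i) {
    out <- NULL
    for (drug in c("velotaxel", "bezoplatin")) {
      st <- as.integer(regexpr(drug, texts[i], fixed = TRUE)) - 1L
      if (st >= 0) out <- rbind(out, data.frame(
        article_id = corp$article_id[i], start = st, end = st + nchar(drug),
        surface = drug, stringsAsFactors = FALSE))
    }
    out
  }))
  model <- suppressWarnings(train_drug_tagger(corp, ent, seed = 5))
  m <- tag_drugs(model, "we gave velotaxel and bezoplatin to the cohort")
  expect_equal(sort(m$surface), c("bezoplatin", "velotaxel"))
  expect_equal(nrow(m), 2L)
})

test_that("mention union prefers model mentions on exact span ties", {
  model_m <- data.frame(surface = "druga", start = 0L, end = 5L,
                        score = 0.9, source = "model",
                        stringsAsFactors = FALSE)
  lex_m <- data.frame(surface = "druga", canonical = "DrugA", start = 0L,
                      end = 5L, source = "lexicon",
                      stringsAsFactors = FALSE)
  u <- combine_mentions(model_m, lex_m)
  expect_equal(nrow(u), 1L)
  expect_equal(u$source, "model")
  u2 <- combine_mentions(model_m[0, ], lex_m)
  expect_equal(u2$source, "lexicon")
})

test_that("filtering never lowers precision on a tagged synthetic corpus", {
  g <- generate_corpus(corpus_config(n_articles = 80, lexicon_size = 40,
                                     seed = 31))
  model <- train_drug_tagger(g$corpus, g$entities, seed = 1)
  pred <- tag_corpus(model, g$corpus)
  rules <- load_filter_rules()
  before <- entity_metrics(pred, g$entities)
  after <- entity_metrics(filter_false_positives(pred, rules), g$entities)
  expect_gte(after$precision, before$precision)
  expect_equal(after$recall, before$recall)  # rules target non-drug shapes
})
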