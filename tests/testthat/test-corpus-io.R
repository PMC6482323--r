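sample_xml <- system.file("extdata", "medline_sample.xml",
                          package = "oncotext")

test_that("Medline XML reading recovers PMIDs, titles and abstracts", {
  corp <- read_medline_xml(sample_xml)
  expect_s3_class(corp, "corpus")
  expect_equal(corp$article_id, c("26000001", "26000002", "26000003"))
  expect_false(anyDuplicated(corp$article_id) > 0)
  # labelled AbstractText sections are joined by single spaces
  expect_equal(corp$abstract[2],
               paste("Maintenance schedules vary across centers.",
                     "Records of imatinib dosing were reviewed",
                     "retrospectively. Continuous dosing was associated",
                     "with longer progression free intervals."))
  # record with no Abstract element yields an empty abstract
  expect_identical(corp$abstract[3], "")
})

test_that("records without a PMID are skipped with a warning", {
  bad <- tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    "<PubmedArticleSet>",
    "<PubmedArticle><MedlineCitation><PMID>1</PMID>",
    "<Article><ArticleTitle>Kept.</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "<PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>Dropped.</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle>",
    "</PubmedArticleSet>"), bad)
  expect_warning(corp <- read_medline_xml(bad), "without PMID")
  expect_equal(corp$article_id, "1")
})

test_that("malformed XML and bad paths raise parse errors", {
  bad <- tempfile(fileext = ".xml")
  writeLines("<PubmedArticleSet><PubmedArticle>", bad)
  expect_error(read_medline_xml(bad), "malformed XML")
  expect_error(read_medline_xml(tempfile()), "no such file")
})

test_that("Medline write/read round-trips a corpus", {
  corp <- read_medline_xml(sample_xml)
  out <- tempfile(fileext = ".xml")
  write_medline_xml(corp, out)
  back <- read_medline_xml(out)
  expect_equal(as.data.frame(back), as.data.frame(corp),
               ignore_attr = TRUE)
})

test_that("typed TSV reading enforces schema and percent range", {
  orth <- read_typed_tsv(
    system.file("extdata", "orthologs_sample.tsv", package = "oncotext"),
    c(human_gene_id = "character", dog_gene_id = "character",
      similarity = "percent"))
  expect_equal(nrow(orth), 7L)
  expect_type(orth$similarity, "double")

  f <- tempfile()
  writeLines(c("human_gene_id\tsimilarity", "ENSG1\t101.0"), f)
  expect_error(read_typed_tsv(f, c(similarity = "percent")), "\\[0, 100\\]")

  writeLines("human_gene_id\tsimilarity", f)
  empty <- read_typed_tsv(f, c(similarity = "percent"))
  expect_equal(nrow(empty), 0L)

  expect_error(read_typed_tsv(f, c(missing_col = "character")),
               "missing_col")
})

test_that("results TSV round-trips article/rule/drug-set triples", {
  recs <- data.frame(article_id = c("7", "3"), rule_id = c(9L, 2L),
                     control_phrase = c("x combination of y", "a plus b"),
                     stringsAsFactors = FALSE)
  recs$drugs <- list(c("paclitaxel", "ABT-737"), c("zeta", "alpha"))
  f <- tempfile(fileext = ".tsv")
  write_results(recs, f)
  lines <- readLines(f)
  expect_equal(lines[1], "article_id\trule_id\tdrugs\tcontrol_phrase")
  # drugs sorted lexicographically and joined by |; rows sorted by id
  expect_match(lines[2], "^3\t2\talpha\\|zeta\t")
  expect_match(lines[3], "^7\t9\tABT-737\\|paclitaxel\t")

  back <- read_results(f)
  expect_setequal(
    paste(back$article_id, back$rule_id, sapply(back$drugs, paste,
                                                collapse = "|")),
    paste(recs$article_id, recs$rule_id,
          sapply(lapply(recs$drugs, sort, method = "radix"), paste,
                 collapse = "|")))

  # determinism: writing the same records twice is byte-identical
  f2 <- tempfile(fileext = ".tsv")
  write_results(recs, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))

  # empty collection -> header-only file
  f3 <- tempfile(fileext = ".tsv")
  write_results(recs[0, ], f3)
  expect_equal(readLines(f3), "article_id\trule_id\tdrugs\tcontrol_phrase")
})

test_that("corpus constructor rejects duplicate or empty ids and titles", {
  df <- data.frame(article_id = c("1", "1"), title = c("a", "b"),
                   abstract = c("", ""), stringsAsFactors = FALSE)
  expect_error(corpus(df), "duplicate")
  df2 <- data.frame(article_id = "1", title = "", abstract = "x",
                    stringsAsFactors = FALSE)
  expect_error(corpus(df2), "title")
})
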