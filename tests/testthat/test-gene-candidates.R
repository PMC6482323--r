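ext <- function(f) system.file("extdata", f, package = "oncotext")

fixture_inputs <- function() {
  list(
    orth = read_typed_tsv(ext("orthologs_sample.tsv"),
                          c(human_gene_id = "character",
                            dog_gene_id = "character",
                            similarity = "percent")),
    som = read_typed_tsv(ext("somatic_catalog_sample.tsv"),
                         c(symbol = "character", entrez_id = "character")),
    idm = read_typed_tsv(ext("idmap_sample.tsv"),
                         c(entrez_id = "character",
                           human_gene_id = "character")))
}

test_that("candidate selection intersects catalog and applies the inclusive 75% threshold", {
  fx <- fixture_inputs()
  expect_message(cand <- select_candidates(fx$orth, fx$som, fx$idm, 75),
                 "no ID mapping")
  # ERBB2 sits exactly at 75.0 and must be included; PTEN at 74.9 must not;
  # the high-similarity non-catalog gene is excluded by the intersection
  expect_setequal(cand$symbol, c("BRCA1", "ERBB2", "KIT", "TP53"))
  expect_true(all(cand$similarity >= 75))
  expect_equal(cand$symbol, sort(cand$symbol, method = "radix"))
  expect_equal(attr(cand, "n_unmapped"), 1L)
})

test_that("empty somatic catalog yields no candidates", {
  fx <- fixture_inputs()
  cand <- select_candidates(fx$orth, fx$som[0, ], fx$idm, 75)
  expect_equal(nrow(cand), 0L)
})

test_that("candidate selection is invariant to input row order", {
  set.seed(41)
  prob <- random_gene_problem(300L, 30L)
  a <- select_candidates(prob$orthologs, prob$somatic, prob$id_map, 75)
  shuf <- function(d) d[sample.int(nrow(d)), , drop = FALSE]
  b <- select_candidates(shuf(prob$orthologs), shuf(prob$somatic),
                         shuf(prob$id_map), 75)
  rownames(b) <- NULL
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("threshold 0 with full catalog coverage returns every human gene", {
  set.seed(42)
  prob <- random_gene_problem(200L, 40L)
  # catalog covering every ortholog human gene
  human <- unique(prob$orthologs$human_gene_id)
  som <- data.frame(symbol = paste0("G", seq_along(human)),
                    entrez_id = as.character(seq_along(human)),
                    stringsAsFactors = FALSE)
  idm <- data.frame(entrez_id = som$entrez_id, human_gene_id = human,
                    stringsAsFactors = FALSE)
  cand <- select_candidates(prob$orthologs, som, idm, 0)
  expect_setequal(cand$human_gene_id, human)
})

test_that("selection matches the brute-force intersection oracle", {
  set.seed(43)
  for (rep in 1:5) {
    prob <- random_gene_problem(400L, 40L)
    got <- select_candidates(prob$orthologs, prob$somatic, prob$id_map, 75)
    want <- brute_candidates(prob$orthologs, prob$somatic, prob$id_map, 75)
    expect_equal(got[c("symbol", "human_gene_id", "dog_gene_id",
                       "similarity")],
                 want, ignore_attr = TRUE)
  }
})

test_that("synonym table keeps source order, drops '-', dedupes case-insensitively", {
  gi <- read_typed_tsv(ext("gene_info_sample.tsv"),
                       c(symbol = "character", synonyms = "character"))
  syn <- build_synonym_table(
    gi,
    hgnc_ids = c(BRCA1 = "1100"),
    omim_ids = c(BRCA1 = "113705"),
    ensembl_human = c(BRCA1 = "ENSG00000012048"),
    ensembl_dog = c(BRCA1 = "ENSCAFG00000014600"))
  expect_equal(syn$BRCA1,
               c("BRACA1", "BRCAI", "BRCC1", "BROVCA1", "FANCS", "IRIS",
                 "PNCA4", "PPP1R53", "PSCP", "RNF53", "HGNC: 1100",
                 "MIM:113705", "Ensembl: ENSG00000012048",
                 "Ensembl:ENSCAFG00000014600"))
  # "-" placeholder gives no synonym terms (and no IDs were supplied)
  expect_length(syn$PTEN, 0L)

  dup <- data.frame(symbol = "X", synonyms = "Abc|ABC|def",
                    stringsAsFactors = FALSE)
  expect_equal(build_synonym_table(dup)$X, c("Abc", "def"))
})

test_that("query builder produces left-nested OR with balanced parentheses", {
  expect_equal(build_pubmed_query("TP53"), "(TP53)")
  expect_equal(build_pubmed_query(c("A", "B")), "((A) OR B)")
  expect_error(build_pubmed_query(character()), "at least one")

  set.seed(44)
  for (n in c(1L, 2L, 5L, 14L, 30L)) {
    terms <- replicate(n, paste(sample(letters, 4), collapse = ""))
    q <- build_pubmed_query(terms)
    expect_equal(lengths(regmatches(q, gregexpr(" OR ", q, fixed = TRUE))),
                 n - 1L)
    opens <- nchar(gsub("[^(]", "", q))
    closes <- nchar(gsub("[^)]", "", q))
    expect_equal(opens, closes)
  }
})

test_that("write_queries emits symbol<TAB>query lines", {
  syn <- list(AAA = c("x", "y"), BBB = "z")
  f <- tempfile()
  write_queries(syn, f)
  expect_equal(readLines(f), c("AAA\t((x) OR y)", "BBB\t(z)"))
})
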