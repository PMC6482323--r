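# oncotext

Text mining of the cancer-therapy literature for comparative oncology:
candidate gene selection, treatment-outcome classification, drug
named-entity recognition and drug-combination extraction, with offline
drug-database cross-referencing.

## What it does

Dogs develop many of the same cancers as humans, and most canine genes are
one-to-one orthologs of human genes, which makes the dog a natural model
for cancer-therapy research. `oncotext` implements the literature pipeline
that such work needs, end to end:

* **Candidate genes.** Cross-reference a human–dog ortholog table (with
  percent protein similarity s) against a somatic-mutation gene catalog: a
  candidate is a pair with s ≥ 75 (inclusive) whose human member is in the
  catalog (`select_candidates()`).
* **PubMed queries.** Per gene, a left-nested boolean OR over its synonym
  and identifier terms: `(((t1) OR t2) OR t3) …` (`build_pubmed_query()`).
* **Outcome classification.** A 300-tree random forest over word-trigram
  counts of the preprocessed title + abstract labels each article
  1 = treatment success, 0 = treatment failure; evaluated by stratified
  10-fold cross-validation with pooled out-of-fold precision/recall/F for
  the success class (`train_outcome_classifier()`, `evaluate_kfold()`).
* **Drug NER.** A maximum-entropy per-token tagger (ridge-penalised
  logistic regression over token identity, prefix/suffix, shape and
  neighbour features) plus a 27-rule regular-expression false-positive
  filter that deletes non-drug surfaces such as `P≤0.001`
  (`train_drug_tagger()`, `filter_false_positives()`).
* **Combination extraction.** Around each match of a combination cue
  ("in combination with", "plus", … — 27 shipped rules) a control phrase
  (cue ± 5 tokens) with left/right 5-token context nodes is built; ≥ 2
  distinct drug names inside those regions form one combination record
  (`extract_all()`).
* **Cross-referencing.** Extracted names are matched against offline
  DrugBank/PubChem/ChemSpider-style tables in priority order; unmatched
  names are flagged as new drugs/substances (`cross_reference()`).
* **Synthetic corpora.** `generate_corpus()` emits Medline-format XML with
  planted drug mentions, outcome language, combination cues and full
  ground truth, so the entire pipeline is testable with no downloads.

## Worked example

```r
library(oncotext)

corp <- read_medline_xml(system.file("extdata", "medline_sample.xml",
                                     package = "oncotext"))
lex <- data.frame(name = c("ABT-737", "paclitaxel", "imatinib"))
mentions <- lapply(article_text(corp), harvest_lexicon_mentions, lexicon = lex)
names(mentions) <- corp$article_id

recs <- extract_all(corp, load_combination_rules(), mentions)
recs[c("article_id", "rule_id", "control_phrase")]
#>   article_id rule_id
#> 1   26000001       9
#>                                                               control_phrase
#> 1 cells were exposed to the combination of ABT-737 and paclitaxel over three
recs$drugs[[1]]
#> [1] "ABT-737"    "paclitaxel"
```

One abstract mentions ABT-737 and paclitaxel around the cue
`combination of` (rule 9), so exactly one combination record is emitted;
the second abstract mentions only imatinib (one drug is never a
combination), and the `P≤0.001` distractor is removed by the
false-positive filter before it can pollute mentions.

On a synthetic corpus at the generator's default study conditions
(n = 2000 articles, 17% failure rate, disjoint outcome vocabularies), the
classifier's 10-fold cross-validation reaches F ≈ 1.0 for the success
class, the tagger recovers planted drugs on held-out articles with
entity-level F ≈ 0.98 after filtering, and extraction recovers the planted
combinations exactly (see below for how to reproduce these numbers).

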