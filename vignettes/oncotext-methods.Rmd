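---
title: "Methods: mining cancer-therapy literature for drug combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining cancer-therapy literature for drug combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotext)
```

## The problem

Comparative oncology treats the dog as a spontaneous model of human cancer:
most canine genes have one-to-one human orthologs, and many tumor types
present similarly in both species. A reference database of cancer
therapies for such work has to be distilled from the literature, which is
far too large to read. `oncotext` implements the distillation pipeline as a
set of composable stages:

1. **Candidate genes** — cross-reference a human–dog ortholog table
   (carrying percent protein similarity) with a catalog of somatically
   mutated cancer genes; a candidate is an ortholog pair whose human member
   is in the catalog and whose similarity is at least 75%.
2. **Queries** — for each candidate, build a PubMed boolean query from its
   synonym table plus HGNC/OMIM/Ensembl identifiers.
3. **Outcome classification** — label each retrieved article as treatment
   success (1) or failure (0) with a random forest over word-trigram
   counts.
4. **Drug NER** — find drug/therapy names with a maximum-entropy per-token
   tagger, then delete false positives with a regular-expression
   dictionary.
5. **Combination extraction** — around each match of a cue phrase ("in
   combination with", "plus", ...), build a context window and record the
   distinct drugs found inside it.
6. **Cross-referencing** — map extracted drug names to offline
   DrugBank/PubChem/ChemSpider-style tables; unmapped names are flagged as
   new drugs/substances.

A synthetic-corpus generator with full ground truth makes every stage
testable offline.

## Candidate genes and queries

`select_candidates()` treats the similarity threshold as **inclusive**
(a pair at exactly 75.0% is a candidate). When several ortholog rows share
one human gene — paralog noise in an ostensibly one-to-one table — the row
with the highest similarity wins, with ties broken by the
lexicographically smallest dog gene ID; this keeps the selection a
deterministic function of the input *set*, not its row order. Somatic
catalog entries whose Entrez ID has no Ensembl mapping are excluded and
counted, never guessed.

Query terms preserve the spacing quirks of their sources verbatim
("HGNC: 1100" with a space, "MIM:113705" without), because the query string
is an interface to PubMed, not display text. The query is a left-nested OR
fold: `(t1)`, `((t1) OR t2)`, and so on — `build_pubmed_query()` emits
exactly this shape so that n terms always produce n − 1 `OR`s and balanced
parentheses.

## Text preprocessing

Tokenization keeps letter-initial words with internal hyphens together
("ABT-737" is one token), keeps decimal numbers whole, and — deliberately —
keeps comparison expressions such as "P≤0.001" or "IC50=20" as single
tokens, because the false-positive filter is defined over exactly those
surfaces. Punctuation tokens are kept for tagging and window counting and
dropped for classification.

The classifier pipeline is: tokenize → lowercase → character normalization
→ stopword removal → Porter stemming. "Spelling normalization" is
implemented as deterministic character normalization (Greek letters spelled
out, dashes and quotes unified, ligatures expanded); no edit-distance
correction is attempted, so the step is reproducible and cannot hallucinate
words. The Porter stemmer is the classic suffix-stripping algorithm,
implemented in the package and pinned by its published example pairs in the
test suite. Stemming is tested for idempotence on stem-stable text, not
universally: a handful of English words (e.g. "proceed") are genuinely not
fixed points of the algorithm.

## Outcome classification

Features are raw counts of word **trigrams** of the preprocessed
title + abstract. The forest uses 300 trees and a fixed seed
(single-threaded, so results are bit-reproducible), with nodes grown to
purity. Two practical controls sit in front of the forest: trigrams must
occur in at least `min_df = 2` training documents, and the vocabulary is
capped at the `max_features = 2000` most document-frequent terms. Both are
standard text-classification hygiene — the discarded tail is dominated by
one-off trigrams that a 300-tree forest cannot use — and both are
recomputed inside each training fold during cross-validation, so no
information leaks from evaluation folds.

`evaluate_kfold()` uses stratified folds and scores the pooled out-of-fold
predictions once. Metrics are reported for the positive (success) class,
with the macro-averaged F alongside, because with a ~17% failure rate the
positive-class numbers alone can look flattering. `eval_metrics()` defines
a metric with a zero denominator as 0.

## Drug NER

The tagger is a per-token classifier of the maximum-entropy family, fitted
as ridge-penalised logistic regression (`glmnet`, Gaussian prior,
λ = 10⁻³) over sparse indicator features: token identity, lowercase form,
2–4 character prefixes and suffixes, word shape ("Xx-ddd"), and the
lowercase neighbours within distance two. Maximal runs of positive tokens
(probability ≥ 0.5) become mentions. The fit is deterministic; the seed is
recorded for provenance.

The false-positive filter drops a mention **iff** a rule pattern matches
its full surface (patterns are anchored by the filter). The shipped
dictionary of 27 rules covers comparison expressions — a letter-initial
token containing `<`, `>`, `=`, `≤` or `≥` followed by a numeric tail,
which is what removes "P≤0.001" — plus percentages, sample-size
expressions, units-style statistics and generic oncology words like
"inhibitor". Because the rules target only non-drug shapes, filtering can
raise precision but never touches recall on true drug names; that
direction is asserted in the tests. Lexicon matching
(`harvest_lexicon_mentions()`) is case-insensitive, token-boundary-anchored
and longest-match; model and lexicon mentions can be unioned with
exact-span deduplication, preferring the model source on ties.

## Combination extraction

For every match of a cue rule, the extractor builds a three-node context
structure: the **control phrase** at the root (the cue extended by up to
five tokens on each side) and left/right child nodes of up to five further
tokens. Distinct drug names (case-insensitive) whose mentions intersect any
of the three regions form one combination record; fewer than two distinct
names produce nothing, and a drug repeated on both sides of a cue is still
one name. Records for identical (article, drug set) pairs from different
rules collapse to the lowest rule id, and output order is deterministic.

Two readings of the control phrase's extent are defensible (cue-only versus
cue ± window); the cue ± window reading is the default and a
`extend_control = FALSE` switch gives the narrower one. Drugs inside the
control phrase count toward combinations under the default. Window units
are tokens of the NER tokenizer, punctuation included. Combinations of
three or more drugs stay one record rather than being exploded into pairs.
The shipped rule set has 27 cue patterns with stable ids; the set is
user-replaceable, and rule 9 is the "(in) combination of/with" family.
Negation ("was **not** combined with") is not handled and is a known
limitation.

## Cross-referencing

Names are matched case-insensitively after character normalization and
hyphen/space unification, against names and synonyms of the database
tables in priority order (drugbank > pubchem > chemspider by default,
configurable); the first table wins. Matching is by name only — no
structure or identifier matching — and that assumption is explicit:
reordering tables can change attribution but never the mapped/unmapped
split, which always partitions the input.

## The synthetic generator

`generate_corpus()` emits Medline-format XML plus ground truth. Its
defaults are the study conditions: 17% failure articles, a 1308-name
lexicon split 656/451/104/97 across drugbank/pubchem/chemspider/new,
fully disjoint outcome vocabularies (`vocab_separation = 1`), a planted
combination in 30% of articles, and statistics-expression distractors in
30%. Abstracts are 3–8 template sentences of roughly 8–20 tokens; drug
names are pronounceable syllable + suffix constructions ("-tinib",
"-platin", ...) plus three real anchors (ABT-737, paclitaxel, imatinib) so
the worked examples run against generated corpora. Combination articles
carry exactly one cue with two distinct drugs placed immediately around
it — inside the five-word windows by construction — and no other drug
mentions, so the planted set is exactly what a correct windowed extractor
recovers, and a brute-force co-occurrence oracle agrees.

What the generator does **not** emulate: real biomedical prose, ambiguous
or nested entity boundaries, misspellings, negated combinations, multiword
drug names in running text, or class imbalance in entity shapes. Passing
tests on this corpus therefore demonstrate that the machinery is correct
and well-calibrated under its own assumptions, not that the printed
performance figures transfer to PubMed-scale data.

## Numerical and design choices

* Sorting everywhere uses C-locale (`method = "radix"`) ordering, so
  output files are byte-identical across locales and repeated runs.
* Offsets are 0-based half-open character positions into the analysis text
  (title + `" "` + abstract); every span slices back to its surface form.
* Forest fits, fold assignment and the generator all run from explicit
  seeds; ranger runs single-threaded so probabilities are reproducible.
* Problem sizes in the test suite — cross-validation at 2000 articles,
  tagging at 500, extraction at 200 — were chosen as the smallest corpora
  at which the stochastic recovery checks are stable across seeds.
* Articles are not filtered by language; the `Language` field is read and
  stored when present.
* The printed shorthand often used for the comparison-expression filter
  rule cannot match its own canonical example, so the rule is implemented
  from its semantics (letter start, comparison operator including ≤/≥,
  numeric tail).

## Limitations

Entity linking beyond exact lexicon matching, negation and scope handling,
live database/PubMed access, and reproduction of production-scale corpus
statistics are out of scope. The classifier's averaging convention
(positive-class metrics) is one defensible reading of single-row
precision/recall/F reporting; macro-averages are logged alongside for
transparency.
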