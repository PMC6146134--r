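---
title: "Methods: ranking abstracts for kinome curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking abstracts for kinome curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinasetriage)
```

## The curation problem

Biocurators maintaining protein knowledge bases triage literature: for a
target kinase and an annotation *axis* — a disease (DIS) or a biological
process (BP) — they must find, among all PubMed abstracts mentioning the
kinase, the few that describe a curatable relation. The unit of work is the
candidate triple `<kinase_id, axis, pmid>`, and the system's job is to rank
each query's candidate documents so curatable ones surface first.

`kinasetriage` implements that pipeline end to end: entity tagging over
PubTator-format abstracts, entity-pair feature extraction into sparse
document-term matrices, pseudo-negative bootstrapping, linear classifiers
that score and rank candidates, and the full retrieval evaluation battery.

## Pipeline and model

1. **Tagging.** Kinase, disease and BP mentions come from a dictionary
   tagger (`tag_dictionary()`): case-insensitive, token-boundary-anchored,
   leftmost-longest matching, except that short all-uppercase symbols
   (≤ 5 characters) match case-sensitively so gene symbols like `WAS` do
   not fire on the word "was". Mutation mentions come from a three-family
   regex tagger (`tag_mutations()`): one-letter substitutions (`V600E`),
   three-letter substitutions (`Ala123Val`) and HGVS-prefixed strings
   (`p.Gly12Asp`). Both are deliberately simple, pluggable stand-ins for
   production gene/disease/mutation taggers, which miss a substantial
   fraction of kinase mentions themselves; the package treats the tagger as
   replaceable input, and every downstream contract is tagger-agnostic.

2. **Features.** For each triple, eleven feature families are computed
   (`extract_features()`): mention counts of the target kinase and the
   axis type (f1–f2); indicators for the kinase/axis appearing in the
   first or last sentence and for a same-sentence co-occurrence (f3–f7);
   counts of seven curation keyword groups (verbs such as *inhibit* and
   *phosphorylate*; patient, genetics, dosage-scale, time-period and
   study-design terms; and a *variation* group whose total is the number of
   mutation mentions); bag-of-words lemma counts around the relevant
   mentions; and two dependency parse-path families between the kinase and
   axis mention heads. All features live in one long tibble and are
   assembled by `build_matrix()` into a sparse matrix whose seven dense
   features occupy reserved leading columns.

3. **Pseudo-negatives.** The candidate pool has no negative labels. A
   one-class SVM is fitted on the positive triples' matrix, the pool is
   scored, and the `k` lowest-scoring rows become pseudo-negative training
   instances (`generate_pseudo_negatives()`), ties broken by ascending row
   key.

4. **Classifiers.** Three families (`triage_fit()`), all trained on both
   axes together: elastic-net-regularized logistic regression (glmnet),
   a binary linear SVM, and the one-class SVM used alone. Scoring
   (`triage_score()`) returns the elastic net's log-odds or the SVMs'
   signed decision values; `rank_triples()` orders each query by
   descending score with ties broken by ascending pmid, making every
   materialized ranking a strict total order.

5. **Evaluation.** `evaluate_run()` computes per query the average
   precision, P@10/30/100, R@30/100, R-precision and the maximum precision
   observed at any rank, plus their means (MAP etc.). A development-triple
   set additionally yields the expected-rank score: the sum over dev
   triples of `rank_in_pool / pool_size` (`escore()`), where a triple
   ranked first among 10 candidates contributes 0.1 and lower is better.
   The raw sum is the headline number; a per-triple mean is reported
   alongside purely for readability.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `bow_window` | 3 tokens/side | bag-of-words context, clipped at sentence boundaries |
| `weighting` | counts | term weighting (`binary`, `tfidf` offered) |
| `alpha` | 0.5 | elastic-net mixing (0 = ridge, 1 = lasso) |
| `nfolds` | 5 | cross-validation folds for the penalty path |
| `cost` | 1 | binary SVM cost |
| `nu` | 0.1 | one-class SVM nu (upper bound on the outlier fraction) |
| `kernel` | linear | SVM kernel; linear behaves predictably on sparse text features |
| `seed` | — | one integer, propagated to every stochastic component |

The bag-of-words window and the term weighting have no canonical value in
the triage literature; 3 tokens and raw counts are conventional starting
points and are exposed rather than hidden. The elastic-net penalty is
chosen by 5-fold cross-validated deviance along glmnet's automatic
log-spaced path.

## Numerical and design choices

* **Offsets.** All mention offsets are 0-based half-open into the full
  text `title + " " + abstract`, validated on load against the surface
  string.
* **Sentence splitting** is rule-based and deterministic: split after
  `.!?` followed by whitespace and a capital/digit, with an abbreviation
  exception list (`e.g.`, `et al.`, `Fig.` …); unsplittable text falls back
  to a single span. A real NLP sentence splitter can be substituted
  upstream since sentences are plain spans on the document.
* **Lemmatization.** Keyword matching uses inflectional variant sets (so
  "inhibits" and "inhibited" both count toward *inhibit*); the bag-of-words
  lemmatizer is a deterministic lowercase-plus-suffix-stripping fallback.
  When dependency parses are supplied (CoNLL-U), their lemmas are used for
  the path features only.
* **Parse paths** are encoded as alternating relation labels with
  direction markers and intermediate lemmas, e.g. `nsubj↑inhibit↓dobj`
  for a kinase subject and axis object of one verb; endpoint surface forms
  are never included. The "without ancestors" variant keeps only the
  relation-label sequence (`nsubj↑↓dobj`): the notion is not precisely
  defined in the triage literature, and dropping every intermediate lemma
  (the lowest common ancestor and any other tokens on the path) is this
  package's reading, chosen because it yields a fully delexicalized,
  low-cardinality feature. When several same-sentence mention pairs exist,
  the closest pair per sentence contributes, keeping the path vocabulary
  bounded. The keyword features emit all seven groups (not only kinase
  verbs), the more inclusive of the two defensible readings.
* **Scoring scale.** The elastic-net score is the log-odds, not the
  probability: confidently ranked candidates push the predicted
  probability to exactly 1.0 in double precision, which would collapse
  their ordering into arbitrary pmid tie-breaks. The log-odds is the same
  quantity under a monotone map, with no saturation.
* **Ties.** Everywhere a ranking is materialized, ties break by ascending
  pmid, so runs, metrics and file outputs are bit-reproducible.
* **Degenerate inputs.** Queries with no relevant documents are excluded
  from MAP with a warning (standard qrels practice); judged-relevant
  documents missing from a run count as unretrieved and contribute zero to
  AP; an empty candidate pool or single-class training input is an error
  naming the violated contract.

## The chance baseline

Signal checks compare a ranking's MAP against the exact expectation under
a uniformly random permutation. For a pool of $n$ documents with $r$
relevant, conditioning on a relevant document at rank $p$ leaves the other
$r-1$ relevant hypergeometrically distributed over the remaining $n-1$
positions, giving

$$E[\mathrm{AP}] = \frac{1}{r} \sum_{p=1}^{n} \frac{r}{n}\,
  \frac{1 + (p-1)\frac{r-1}{n-1}}{p},$$

implemented in `expected_random_ap()` and verified against Monte Carlo
simulation in the test suite. `expected_random_map()` averages it over a
run's evaluable queries.

## The synthetic corpus

Real kinome triage corpora are private; the package therefore ships a
generator (`generate_corpus()`) whose documents are built from slot-filled
sentence templates: kinase names `KIN1..KINn`, one disease and one BP term
per document, curation keywords, mutation strings, and filler tokens. The
planted structure mirrors what separates curatable from background
articles: a positive triple's document contains its kinase and its focal
axis term in the *same sentence* with probability `p_same_sentence_pos`
(default 0.9) and keyword enrichment with probability `p_keyword_pos`
(0.8); background and pool documents use the background rates (0.1 /
0.2) for every axis. Every document names its kinase in the title and
carries one term of each axis, so bare term presence is not the signal —
the co-occurrence structure is. Mutation mentions are planted in 30% of
positive documents, exercising the variation keyword group (in a null
configuration this rate should also be set to 0, since it is planted
signal). Gold dependency parses are emitted for every templated relation
sentence, so parse-path features are testable without a real parser, and
gold mention annotations for every planted entity.

The default profile (255 positives, 250 negatives, 22 development triples,
a 2000-document unlabeled pool over 20 kinases) is a one-tenth-scale
replica of the kinome triage corpus shape (2550 / 2500 / 225 over a large
candidate pool); the scale keeps a full train-bootstrap-rank-evaluate
cycle around a minute on one CPU, and those are the problem sizes the test
suite runs. Identical configuration and seed give byte-identical output
files.

**What passing tests do and do not show.** The generator emulates the
*structure* of the triage signal, not biomedical language: its vocabulary
is tiny, its sentences are templated, its taggers therefore operate at
perfect recall, and its feature space is low-dimensional and clean. Signal
recovery on this corpus demonstrates that the pipeline's plumbing,
features, bootstrapping and metrics are correct — not that any classifier
would reach a particular score on real abstracts. One visible consequence:
on such clean, low-dimensional data a margin-based linear SVM can edge out
the cross-validated elastic net on MAP even while the elastic net leads on
the expected-rank score, whereas the elastic net's advantage on real
corpora comes precisely from regularizing noisy, high-dimensional text
features that the generator does not emulate.

## Known limitations

* The dictionary tagger performs no gene normalization (species or
  ambiguity resolution) and no abbreviation expansion; the mutation regex
  covers common substitution and HGVS forms only.
* Parses are consumed, never produced: without a CoNLL-U file the two
  path-feature families are simply absent.
* SVM scores are uncalibrated decision values; only the elastic net's
  scores have a probabilistic reading (via `plogis()`).
* The CNN-style classifier family from the neural triage literature is out
  of scope: it depends on large pre-trained embeddings and was not
  competitive with the linear models on this task.

## A worked run

```{r, eval = FALSE}
synth <- generate_corpus(synth_config(n_positive = 30, n_negative = 20,
                                      n_dev = 8, n_pool = 100,
                                      n_kinases = 5, seed = 7))
ex <- triage_experiment(synth, model = "glmnet", seed = 3)
glance(ex$eval)          # MAP, P@K, R@K, R-Prec, max precision, Escore
expected_random_map(ex$run, synth$qrels)  # chance baseline
autoplot(ex$eval)        # per-query AP
tidy(ex$model)           # surviving elastic-net coefficients
```
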