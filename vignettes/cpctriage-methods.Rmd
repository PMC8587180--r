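---
title: "Methods: corpus-based triage of patient questions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: corpus-based triage of patient questions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpctriage)
```

## The classification model

`cpctriage` treats taxonomy assignment as nearest-neighbour retrieval in a
bag-of-words vector space. A *reference corpus* of labeled texts defines the
space: either one short *description* per category (mode D), a set of
labeled *example* questions carrying 1–3 category codes each (mode E), or
their concatenation (mode D+E). Classification of an unlabeled query then
proceeds in two steps: transform the query into a TF-IDF vector with the
model fitted on the reference corpus, and rank categories by cosine
similarity against the reference vectors.

The TF-IDF convention is the common "default" smooth-IDF setup:

* term frequency is the raw in-document count (no log scaling, no binary
  clipping);
* `idf(t) = ln((1 + N) / (1 + df(t))) + 1`, where `N` is the reference
  corpus size and `df(t)` the number of reference documents containing `t`
  — so `idf == 1` exactly when a term occurs in every document, and no term
  is ever dropped by document-frequency pruning;
* every nonzero document vector is L2-normalized, so the cosine between two
  documents is simply their dot product.

A category's relevance to a query is the **maximum** cosine over reference
documents carrying that category's label. Max-aggregation is the natural
reading of "classify into the most relevant category": one strongly matching
example suffices, and adding reference material can only help (the fused
D+E score of a category is never below its D-only or E-only score in a
shared vector space). Mean-aggregation is available
(`rank_categories(..., aggregate = "mean")`) for sensitivity analysis; it
penalizes categories with heterogeneous reference texts.

### Assumptions and their consequences

The model is purely lexical. Two texts about the same worry phrased with
different words score zero against each other, and a single shared
high-IDF token can dominate a ranking. This is the known failure mode of
bag-of-words cosine retrieval, and the reason the evaluation protocol below
reports distribution-level agreement separately from per-query accuracy:
aggregate surveys can remain faithful at modest individual accuracy, because
misassignments tend to land on prevalent categories.

## Numerical and procedural choices

* **Vocabulary order** is lexicographic (C locale, radix sort), and column
  indices are contiguous — fitting is invariant to document order and
  reproducible across platforms.
* **Tie-breaking.** Categories at exactly equal score are ordered by
  ascending code, compared numerically segment by segment (`1.2 < 1.10 <
  2`), then stable in reference order. Frequency-table ties break the same
  way. This removes all dependence on hash or insertion order.
* **Zero vectors.** A query that tokenizes to nothing (empty, digits,
  punctuation) or shares no vocabulary with the reference corpus yields an
  *empty ranking*, never an arbitrary assignment. Zero-ranking queries are
  excluded from frequency counts but remain, by default, in share
  denominators (`count_empty_in_total = TRUE`), mirroring surveys that
  report shares of the full classified set.
* **IDF statistics come from the reference corpus only.** Queries are
  transformed with the fitted model and do not update `df`. This keeps the
  classifier deployable on streaming queries and makes predictions
  independent of what else happens to be in the batch. Refitting on a fused
  corpus is possible by passing a prefitted `model` to `build_index()`.
* **Serialization.** A fitted model round-trips through JSON
  bit-identically because IDF is recomputed on load from the integer pair
  `(N, df)` rather than parsed from decimal text.
* **Code dialects.** Category codes are stored canonically without the
  trailing dot some printed tables use (`16.3.1.1`, not `16.3.1.1.`);
  writers can restore the trailing-dot dialect. Multi-label fields use `;`
  in TSV (printed tables often use `/`, which is kept out of the on-disk
  dialect to avoid ambiguity) and JSON lists in JSONL.
* **Rounding.** Human-readable percentages round half-up to one decimal
  (`round_half_up()`), matching how published tables print shares; all
  internal computation is full precision.

## Evaluation protocol

A prediction is *correct at k* when at least one of the query's (up to
three) gold categories appears among the top-k ranked categories; `Acc@k`
is the fraction of labeled queries with a hit. Queries whose gold set is
empty — e.g. questions with no corresponding category in the taxonomy — are
excluded from accuracy denominators but retained everywhere else
(classification, frequency reporting). Because top-k hit sets are nested,
`Acc@k` is non-decreasing in `k`; the test suite asserts this on every
benchmark row.

The example-based and fused methods are evaluated by k-fold
cross-validation (default 5): the labeled example corpus is shuffled with
an explicit integer seed, split into near-equal folds (sizes differ by at
most one; every document validates exactly once), the reference index is
refitted per fold on the training folds (plus the full description corpus
in mode D+E), and per-fold accuracies are aggregated as mean, median and
the unbiased n−1 sample SD. Fold assignment is a uniform shuffle, not
stratified: with hundreds of categories over a few hundred documents,
per-category stratification is undefined. The description-based method
needs no cross-validation — the description corpus is fixed — so it is
evaluated single-pass, without SD or median.

Distribution-level agreement uses the Jensen–Shannon divergence with the
`0·log(0/x) ≡ 0` convention, zero-extension onto the union support, and the
natural logarithm by default (bounded by `ln 2 ≈ 0.693`); base 2 is
switchable. Natural log is the common convention when no base is stated.

## The synthetic benchmark generator

No real patient-question corpus ships with the package, and the published
corpora this class of study draws on are not publicly deposited. The
generator (`synthetic_config()`, `generate_synthetic()`) instead emulates
the *structure* of such a study, with defaults pinned to the study
conditions it stands in for:

| parameter | default | what it emulates |
|---|---|---|
| `n_level1`, `n_level4` | 16, 631 | taxonomy breadth at levels 1 and 4 |
| `n_labeled_examples` | 456 | manually labeled example questions |
| `n_queries`, `out_of_taxonomy_rate` | 1000, 0.546 | annotated sample in which 54.6% of questions had no corresponding category |
| `multi_label_probs` | (0.60, 0.35, 0.05) | 1–3 labels per question, mean 1.45 — matching 661 cumulative labels over 456 questions |
| `zipf_exponent` | 1.0 | long-tailed category prevalence |
| `doc_length` | 40 tokens | question length (Poisson, minimum 1) |
| `signature_terms`, `signature_rate` | 8, 0.7 | per-category signature vocabulary and how strongly questions commit to it |
| `desc_signature_terms`, `desc_length` | 2, 10 | short descriptions carrying only the canonical wording plus generic filler |
| `colloquial_rate` | 0.7 | fraction of questions avoiding the canonical wording entirely |

Each fourth-level category owns a disjoint signature vocabulary
(`cat017_sig03`-style tokens) over a shared background vocabulary; a
question's tokens are signature with probability `s = signature_rate` and
background otherwise. Out-of-taxonomy queries draw from background plus a
held-out novel-topic vocabulary (the emergent-topic analogue) and carry no
gold labels. A single master seed derives independent per-stream sub-seeds
(descriptions, examples, queries), so enlarging one corpus never perturbs
another; generation is byte-reproducible.

**Register mismatch.** The generator deliberately separates the
*description register* from the *question register*: descriptions contain
only a category's `desc_signature_terms` canonical terms, while a
`colloquial_rate` fraction of questions draws signature tokens exclusively
from the remaining colloquial terms. This models the empirical observation
that survey-style category descriptions share little vocabulary with how
patients actually phrase questions, and it is what makes the
description-only method markedly weaker than the example-based methods on
the benchmark — the qualitative ordering `D ≪ E ≈ D+E`, with `Acc@10`
well above `Acc@1` for D. Without it (set `colloquial_rate = 0`), short
descriptions are nearly perfect classifiers, because their high-IDF
signature terms face no competing vocabulary: an idealized regime the test
suite uses where exact recovery (`Acc@1 = 1`) is the expected outcome.

**What the generator does not model:** morphology and tokenization noise of
real languages (Japanese question text needs a part-of-speech analyzer,
exposed only as a plug-in contract), emoji and formatting noise of QA
sites, semantic relatedness between categories (signatures are disjoint, so
inter-category confusion arises only through shared background vocabulary),
and annotator disagreement. Passing benchmarks therefore demonstrate
correctness of the pipeline and the *shape* of method differences, not the
absolute accuracy attainable on real text.

**A finding worth noting:** on paired-seed simulations the JSD between
predicted and gold category distributions falls steeply as the signature
rate grows from zero, then flattens into a small-sample floor (from roughly
`s ≈ 0.3` at benchmark sizes). Above the floor, residual errors land
mostly on prevalent categories and preserve the distribution — the same
mechanism that lets distribution-level surveys stay faithful when per-query
accuracy is modest. Tests of the monotone decrease therefore contrast the
steep region with the plateau rather than two points on the plateau.

## Problem sizes used by the test and benchmark suite

Module tests run on toy corpora of 4–16 documents with hand-checkable
vocabularies. Oracle-equivalence checks run the from-scratch TF-IDF against
an independent dense implementation on 100 random toy corpora (agreement to
1e-9 per weight) and the ranker against exhaustive enumeration on 200
random instances (1e-12). The parameter-recovery benchmark uses 50
fourth-level categories, 400 labeled examples and 300 queries — large
enough for stable accuracy estimates, small enough that the whole suite
runs in well under a minute — with chance levels measured by a 30-permutation
label-shuffling null.

## Known limitations

* Bag-of-words cosine cannot use context; no n-grams, stop lists or
  embeddings are provided, by design — the package implements and evaluates
  the standard baseline, not its successors.
* Brute-force search is used throughout; at the intended scale (≤10⁴
  reference documents) this is fast, and no approximate-nearest-neighbour
  index is included.
* Per-category precision/recall/F1 are out of scope; the protocol is
  hit-based `Acc@k` plus distribution divergence.
* Frequency reporting assumes top-1 assignment counts; when a published
  table's percentage column disagrees with its own counts, shares are
  recomputed from counts.
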