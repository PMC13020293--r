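---
title: "Methods: cluster-based topic exploration of biomedical literature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-based topic exploration of biomedical literature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litmapr)
```

## Overview

`litmapr` implements a pipeline for assisted exploration of biomedical
literature: boolean search construction from synonym ("alias") groups,
ingestion of PubMed efetch XML, cluster-based topic modelling with
centroid ranking and topic-word extraction, per-topic meta-information
profiles, a label-driven semantic relation graph, and evaluation
statistics. This vignette records the modelling assumptions, defaults and
design decisions.

## Search construction

A search consists of at most two alias groups. Within a group, phrases
are joined with `OR`; groups are parenthesised and joined with `AND`.
Phrases are emitted bare — no quoting and no field tags — because the
intended consumer is PubMed's default query parser, which applies its own
automatic term mapping. A request for three or more groups is rejected at
validation time rather than silently truncated: the two-group limit is a
deliberate design boundary, and silently dropping a group would change
the search semantics without the user noticing.

Keyword specificity is the mean character count over *all* phrases of
both groups in a single averaging step (not per-group-then-overall).
Counting is Unicode code-point based and includes internal spaces;
surrounding whitespace is trimmed when the group is built.

## Corpus ingestion

`parse_pubmed_xml()` consumes the `PubmedArticleSet` efetch dialect.
Decisions for under-specified fields:

* **Body text** is all `AbstractText` sections joined with newlines.
  Full-text retrieval is out of scope; when a record carries more text in
  its XML it is preserved, but nothing further is fetched.
* **Year**: `PubDate/Year` is preferred; otherwise the first four-digit
  substring of a `MedlineDate` (which covers ranges like "1998 Nov-Dec");
  otherwise `ArticleDate/Year`; otherwise unknown (`NA`). Known years are
  validated into [1800, 2100].
* **MeSH** terms are descriptor names only; qualifiers are ignored.
* Articles with neither title nor abstract carry no usable text and are
  dropped with a warning.

The JSONL cache stores one record per line and round-trips losslessly;
record order always equals XML article order because that order is the
retrieval ranking.

`fetch_publications()` needs network access; its HTTP layer is an
injectable `transport` function so the parsing contract is exercised
against recorded fixtures, never live calls, in the test suite.

## Embedding

The embedding layer is a three-function contract — `embed_documents()`,
`embed_terms()`, `embed_phrase()` — sharing one vector space of dimension
`d`. The package ships a deterministic feature-hashing embedder: tokens
hash to signed buckets (polynomial rolling hash modulo a prime below
2^26, so all arithmetic is exact in doubles), documents are L2-normalised
signed term-frequency vectors, and a word is its signed one-hot bucket
vector. This gives a genuine joint document–word space in which texts
sharing vocabulary are provably more similar, which is exactly the
property the planted-topic tests need, and it is bit-reproducible for a
fixed seed. It does **not** model synonymy or word order, so nothing
about real-corpus semantic quality follows from the tests passing; a
production deployment would plug a pretrained sentence encoder into the
same contract. Multi-word search phrases are embedded as whole phrases
through `embed_phrase()` (not per-token averages), so term nodes and
documents are directly comparable.

The document text is `title + " " + body_text`. The default dimension is
256: large enough that two 200-term topic vocabularies rarely collide in
the same signed bucket, small enough to keep test runtimes trivial.

## Topic modelling

The pipeline is reduce → cluster → centroid:

* **Reduction.** The default reducer is PCA to 5 components
  (`pca_reducer()`), matching the conventional pre-clustering output
  dimensionality. The reducer is an injected function, so a nonlinear
  manifold method with UMAP semantics can be substituted without touching
  the rest of the pipeline; PCA is the default because it is exactly
  reproducible, which the test suite and the acceptance checks rely on.
* **Clustering.** `density_clusterer()` implements hierarchical
  density-based clustering: core distances (distance to the
  `min_samples`-th neighbour) smooth the metric into mutual-reachability
  distances, a single-linkage hierarchy is condensed so only components
  with at least `min_cluster_size` points count as clusters, and the flat
  clustering is selected by excess-of-mass stability. The topic count
  therefore emerges from density structure; sparse documents become noise
  (`NOISE_TOPIC`, id 0). One simplification relative to the reference
  formulation: when a split leaves both children below the minimum size,
  all points of the dissolving cluster are recorded as leaving at that
  split's density level rather than at their individual levels — on
  separated data the extracted clusters are identical. Defaults:
  `min_cluster_size = 15`, `min_samples = min_cluster_size`,
  `allow_single_cluster = TRUE` (so a corpus forming one dense blob is
  one topic, not all-noise). All-noise outcomes return a zero-topic
  model — an explicit "no topics found" result, not an exception.
* **Centroids** are arithmetic means of member document vectors in the
  original embedding space; the reduced space is used only for
  clustering. Ranking within a topic is cosine-to-centroid, ties broken
  by publication id ascending, with a default of the ten most relevant
  members per topic.

Noise documents stay unassigned by default; no nearest-centroid
reassignment is performed because relevance statements about a topic
should rest on documents the density structure actually supports.

Topic words are available two ways, since either may be preferred for
display: nearest word vectors to the centroid (joint-space semantics),
and class-based pseudo-document weighting
`tf(t,c) · log(1 + A/f(t))`. The tokeniser lowercases, splits on
non-alphanumerics and drops tokens shorter than two characters; no
stopword list is applied, because the inverse class weighting already
demotes terms present in every pseudo-document.

## Topic profiles

`build_topic_profile()` counts MeSH descriptors, chemicals and author
keywords across a topic's records, deduplicating within each record so a
count never exceeds the topic size, plus a publication-year histogram
that simply omits unknown years. "MeSH categories" are counted at
descriptor level (not collapsed to tree branches): descriptor names are
what the efetch XML carries, and collapsing would need the MeSH tree as
an extra data dependency. Tables sort by count descending, then name
ascending; rendering charts is the caller's concern.

## Relation graph

Relevant publications sharing a user label are aggregated into a topic
vector: mean of member vectors, then L2-normalised (mean-then-normalise
keeps all node vectors on the unit sphere, so edge weights are pure
cosines). Graph nodes are user topics (red), group-1 phrases (green) and
group-2 phrases (blue), with phrases embedded by the same embedder as the
documents. Each *topic* node contributes undirected edges to its `k = 3`
most similar other nodes — topics or terms; term nodes receive edges but
do not initiate them, because connections are defined per user topic. A
flag (`terms_initiate`) flips that behaviour. Ties at the k-th similarity
break by node id ascending; duplicate edges merge without changing
weight. No topic-model refinement from labels is performed: only graph
regeneration is defined behaviour.

## Evaluation statistics

* **User-agreed relevance** counts only topics with at least one relevant
  label: `100 × relevant-in-counted-topics / suggested-in-counted-topics`.
  With no relevant topic the value is undefined and reported as such,
  never as 0%. Reported means are rounded to one decimal; internal values
  are unrounded. Per-search percentages are averaged with equal weight
  per search.
* **Reference-rank statistics** use 1-based positions (result lists are
  1-based to users); ids absent from the ranking are dropped and counted,
  and the histogram bins are `[1, w], (w, 2w], …` with `w = 50` by
  default.
* **Correlates** of relevance (result volume, keyword specificity) are
  reported as Spearman rank correlations — robust to monotone but
  nonlinear relationships; a constant series is reported as undefined.
* **C_v coherence**: boolean sliding windows (a document shorter than the
  window yields one window) define occurrence probabilities; each topic
  word's context vector holds its ε-smoothed NPMI against all N topic
  words; a word's score is the cosine of its vector with the sum over all
  N vectors, and the topic score is the word mean. Defaults are the
  measure's canonical values: top 10 words, window 110, ε = 1e-12. Words
  absent from the corpus fall back to ε probabilities; a topic with no
  present words is `NaN` and excluded from the corpus mean. In the
  perfect co-occurrence limit all NPMI entries coincide, so the score is
  exactly 1 — a useful calibration case.

## Synthetic corpus generator

The generator emulates what the pipeline assumes about PubMed data, with
planted ground truth: each topic owns an exclusive vocabulary slice and
shares an `overlap` fraction with all topics; documents draw 80–200
tokens from a Zipf(1.1) unigram distribution over a topic-specific
vocabulary ordering; titles are 6–12 tokens; MeSH/chemical/keyword values
come from per-topic pools; years are uniform over the configured range.
The Zipf exponent and length range were chosen once to make clusters
recoverable under the hashing embedder while keeping documents
abstract-sized; they are generator properties, not estimates of PubMed
statistics. What the generator does *not* emulate: real biomedical
language, synonymy, correlated metadata, or citation structure — so
passing tests demonstrate pipeline correctness, not linguistic quality on
real corpora.

`generate_reference_ranking()` plants relevant documents as a contiguous
block ending at rank `round(depth · N)` (`depth = 1` is the tail), other
documents fill the remaining ranks in seeded random order, and `noise`
relocates each relevant document with that probability. With
`noise = 0` the mean rank is exactly `round(depth·N) − (R−1)/2`, a
closed-form oracle for the rank-statistics code.

## Problem sizes and determinism

The test suite and the acceptance script work at deliberately small
scale: corpora of 60 documents (2 topics × 30), embedding dimension 256,
20 seeded replicates for topic-recovery rates, toy corpora for the
brute-force oracles. These sizes give exact planted-structure recovery
and keep the full suite in seconds while exercising every code path;
they are package choices, and all stochastic steps run under explicit
seeds through an RNG guard that restores the caller's random state.

## Known limitations

* The hashing embedder is a testing device; semantic claims on real
  literature require a real encoder behind the embedder contract.
* PCA cannot unfold nonlinear manifolds; strongly curved embedding
  geometries may need a manifold reducer injected.
* The density clusterer is quadratic in corpus size (full distance
  matrix); it is comfortable to a few thousand documents, which covers
  typical per-search corpora.
* `fetch_publications()` performs no rate limiting beyond single
  sequential requests and no retry/backoff loop; heavy programmatic use
  should go through a dedicated E-utilities client.
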