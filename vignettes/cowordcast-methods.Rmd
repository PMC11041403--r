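---
title: "Background-enhanced co-word trend forecasting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Background-enhanced co-word trend forecasting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Co-word analysis reads the thematic structure of a literature from keywords
that co-occur within the same publication. `cowordcast` applies it to the
intersection of artificial-intelligence methods and biomedical topics: given
a corpus of dated abstracts, it builds a time-binned co-occurrence tensor
`counts[t, i, j]` — the number of documents in semiannual bin `t` whose
abstract mentions both AI keyword `i` and biomedical keyword `j` — and
forecasts each cell's future value.

The forecasting idea is *background enhancement*. A technology that works
for one disease tends to spread to similar diseases; a model family tends to
diffuse into fields where its variants already appear. If the keyword axes
are ordered so that semantically similar terms are adjacent, that diffusion
becomes *spatial* structure in the matrix: a cell's future depends not only
on its own past but on the past of its neighborhood. The forecaster
therefore uses the flattened `w x w` window around a cell in bin `t - 1` as
the feature vector for predicting the cell at bin `t`, with `w = 1`
degenerating to the keyword-only baseline.

## Pipeline

1. **Ingestion** (`read_corpus`, `filter_span`, `preprocess_corpus`).
   Records carry an id, a month-resolution date, title and abstract.
   Preprocessing lowercases, deletes digits and punctuation except `-`
   (which links compound terms), and rewrites multiword keywords into
   single tokens (`machine learning` becomes `machine+learning`), matching
   longer phrases first so that nested phrases cannot corrupt each other.
   Counting uses the abstract only by default; the title can be included
   with a flag. Year-only dates are assigned July, the mid-year month.
2. **Embeddings** (`train_embeddings`). One vector per token, default 300
   dimensions and a symmetric context window of 5 tokens. See "Embedding
   trainer" below for what is under the hood.
3. **Keyword selection** (`build_keyword_set`). Candidate terms are ranked
   by document frequency; each is routed to the AI or biomedical domain by
   comparing its mean cosine similarity against two reference term sets (a
   MeSH-style biomedical phrase list; a list of AI algorithm names). The
   top 500 AI and top 1000 biomedical terms are kept by default. A tie of
   the two means routes to the biomedical side — the larger axis — and both
   means are retained in the output for audit.
4. **Tensor construction** (`cluster_order`, `count_tensor`). Each axis is
   ordered by the dendrogram leaf order of agglomerative clustering on
   cosine distance (average linkage by default), so similar keywords sit in
   adjacent rows/columns. Co-occurrence is document-level: repeated
   mentions inside one abstract count once.
5. **Forecasting** (`build_training_set`, `fit`, `predict_bin`,
   `recurrent_forecast`, `window_size_sweep`). To predict bin `t`, the
   model is trained on *all* prior transitions (features from bin `s - 1`,
   target at bin `s`, for every `s < t`), then applied to bin `t - 1`.
   Accuracy is the coefficient of determination over all cells. Multi-step
   forecasts roll forward recurrently: each predicted matrix becomes the
   feature source for the next step.
6. **Trend tables** (`proportion_table`, `growth_table`). Proportion is
   `100 * pair count / document total` over a period; growth is
   `100 * (recent - past) / past` restricted to pairs whose past count
   reaches a threshold (default 10), because tiny bases otherwise produce
   huge meaningless percentages.

## Embedding trainer

No skip-gram trainer is available in this package's dependency footprint,
so `train_embeddings` implements the classical count-based equivalent:
windowed word-context co-occurrence counts are converted to positive
pointwise mutual information and factorized by truncated SVD, with the
embedding `U * sqrt(S)`. This factorization is the well-known closed-form
counterpart of skip-gram with negative sampling, exposes exactly the two
contract parameters (dimensionality, window), and is fully deterministic —
component signs are fixed by the largest-magnitude loading, so the same
corpus always produces bit-identical vectors without any single-thread
caveats. Vectors read/write the standard word2vec text format, so an
externally trained table can be dropped in via `read_word2vec()`.

The 2-D inspection projection (`project_2d`) is a deterministic principal
component projection rather than t-SNE (no t-SNE implementation in the
footprint); it is used only for visual inspection of embedding quality and
plays no role in any computation.

## Regression backends

Six backends are exposed through `fit()`, with their conventional default
hyperparameters:

| backend | implementation | default penalty |
|---|---|---|
| `ridge` | closed form | `RSS + ||w||^2` |
| `lasso` | glmnet, fixed penalty | `1/(2n) RSS + |w|_1` |
| `elastic_net` | glmnet, fixed penalty | `1/(2n) RSS + 0.5 |w|_1 + 0.25 ||w||^2` |
| `svr` | primal BFGS, linear kernel | `0.5 ||w||^2 + sum max(0, |r| - 0.1)^2` |
| `omp` | greedy, OLS refit | keeps `max(1, floor(0.1 p))` coefficients |
| `passive_aggressive` | online PA-I updates | `C = 1`, epsilon 0.1 |

Numerical notes a maintainer should know:

* Features are standardized per column inside the pipeline (constant
  columns pinned at 0) for every backend; this reproduces the historical
  `normalize=True` behavior of older regression libraries in an explicit,
  testable form. Reported coefficients are folded back to the original
  feature scale.
* glmnet internally rescales the response by its population standard
  deviation. For a *fixed* user penalty this silently divides the L2 part
  of the documented objective by `sd(y)` while leaving the L1 part intact;
  `fit()` remaps `(lambda, alpha)` so the solved objective is exactly the
  one written above. The test suite pins this against an independent
  coordinate-descent implementation.
* The SVR backend is *linear* (squared-epsilon-insensitive loss, solved in
  the primal): no kernel-SVM library is available in the footprint, so the
  conventional RBF default is out of reach. For count matrices whose
  dynamics are locally near-linear this is a reasonable stand-in, but it is
  a deviation worth knowing about.
* Predictions are clamped at 0 and left real-valued: targets are counts,
  but accuracy is evaluated on raw predictions.
* Window cells outside the matrix are padded with 0 — beyond the top-k
  keyword grid, co-occurrence is unobserved and sparse.
* Features come from one lag only (the previous bin), matching the
  semiannual design; multi-lag stacking is deliberately not a default.
* In recurrent forecasting the model is fit once, on observed transitions
  only. Predicted matrices are features, never training targets — training
  on one's own predictions would compound bias.

## Synthetic worlds

Every statistical claim in the test suite is grounded in a generator with
known truth (`trend_scenario`, `generate_tensor`, `generate_corpus`):

* Per-pair base intensities are Gamma(shape 4) around `base_rate`
  (coefficient of variation 0.5) — keyword-pair popularity is heterogeneous
  in real corpora.
* A pair's trajectory multiplier is constant, linear, exponential, or a
  changepoint; negative intensities are a scenario error, not clamped.
* Spatial correlation is one pass of 8-neighbor averaging over each bin's
  intensity grid with weight `spatial_corr` — precisely the structure the
  background window is claimed to exploit.
* Counts are Poisson draws around the intensity; everything is reproducible
  from the scenario seed.
* `generate_corpus` realizes a tensor as actual documents: each planted
  co-occurrence becomes one abstract containing exactly one AI and one
  biomedical keyword (multiword keywords in unmerged surface form, so the
  merge rule is exercised end-to-end), plus keyword-free filler documents.
  Counting the generated corpus reproduces the planted tensor *exactly*,
  which is the module's core oracle.

What the generator does **not** emulate: real linguistic text, corpus-level
topic drift, documents mentioning three or more keywords at once, and the
extreme sparsity of a real 500 x 1000 grid. A green test therefore
establishes correctness of the counting, ordering, regression and ranking
machinery and the *qualitative* superiority of the windowed features on
spatially correlated dynamics — not the headline accuracy numbers obtainable
only from a multi-million-document corpus.

## Design choices where the design was open

* **Document frequency, not token frequency**, ranks keywords: the
  co-occurrence analysis is document-level, and the two should agree.
* **Counting basis**: abstract only by default (configurable), since
  co-occurrence is defined on abstracts.
* **Clustering per axis**, not jointly: the two axes are separate semantic
  spaces and each matrix dimension needs its own ordering.
* **Leaf order** is the clustering tree's canonical dendrogram order
  without optimal-leaf reordering, which keeps the order a pure function of
  the merge history.
* **Log heat** is `log10(1 + n)` so empty cells map to zero heat.
* **Growth formula** `100 * (recent - past) / past` with a default past
  threshold of 10: the standard percentage-growth definition; the threshold
  is configurable and recorded in output metadata.
* **Mean accuracy aggregation** starts at the third bin — the first bin has
  no history and the second has no *prior* transition to train on.
* **Evaluation mask**: accuracy is computed over all cells (configurable in
  principle; the grid is dense in synthetic worlds, and restricting to
  nonzero cells would couple the metric to sparsity).

## Parameter recovery and estimator bias

On synthetic tensors generated as `y_t = a * mean(window_{t-1}) + noise`,
ridge and lasso recover `a` (as the sum of fitted window coefficients)
within 10% at 500+ training rows: ridge's default penalty is vanishing in
normalized units, and lasso's soft-threshold bias is absolute, hence
negligible at realistic count scales. The elastic net under its default
penalty does **not** meet such a bound — its L2 term shrinks standardized
coefficients by a scale-free factor (about one third for independent
features; measured ~18% on correlated window features), a structural
property of the estimator rather than an implementation defect. The
recovery test is therefore asserted for ridge and lasso; the elastic net
remains a fully supported forecasting backend (shrinkage costs little in
predictive terms, which is why it exists).

## Known limitations

* The embedding trainer is count-based; contextual embeddings are out of
  scope by design.
* The SVR backend is linear, not RBF (see above).
* The pipeline holds the tensor and embeddings in memory; the intended
  scale is up to a few thousand keywords per axis, not open-vocabulary.
* Trend tables from *predicted* tensors inherit the forecaster's bias at
  long horizons; the recurrent accuracy trace quantifies that decay and
  should accompany any forward-looking table.
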