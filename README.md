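# cowordcast

Background-enhanced co-word trend forecasting for biomedical literature.

## What problem this solves, and for whom

Bibliometric co-word analysis infers the thematic structure of a field from
keywords that co-occur in the same publication. `cowordcast` is for
researchers who want to go one step further and *forecast* which
(AI technology, biomedical field) combinations will grow: it turns a corpus
of dated abstracts into a semiannual co-occurrence tensor

```
counts[t, i, j] = # documents in time bin t mentioning both
                  AI keyword i and biomedical keyword j
```

and predicts future bins of that tensor. The keyword axes are ordered by
agglomerative clustering of word embeddings (cosine distance, dendrogram
leaf order), so semantically similar terms occupy adjacent rows/columns.
That ordering is what makes the core idea work: **background-enhanced
prediction** forecasts a cell not from its own history alone but from the
flattened `w x w` spatial window around it in the previous bin,

```
y[t](i,j) ~ f( counts[t-1, i-h : i+h, j-h : j+h] ),    h = (w-1)/2,
```

because technologies diffuse across *similar* fields and fields adopt
*similar* technologies. `w = 1` is the keyword-only baseline; on spatially
correlated dynamics `w = 3` beats it (this is asserted in the acceptance
suite). Forecast accuracy is the coefficient of determination
`R^2 = 1 - SS_res / SS_tot` over all cells of a predicted bin; multi-step
forecasts roll forward recurrently with each prediction feeding the next
window, and ranked trend tables report the proportion of publications per
pair and threshold-filtered percentage growth between periods.

Six regression backends are available behind one interface
(`ridge`, `lasso`, `elastic_net`, `svr`, `omp`, `passive_aggressive`), and
a synthetic-world generator with known ground truth (`trend_scenario`,
`generate_corpus`) makes every stage testable without external data.

## Worked example

Simulate a world with linearly growing, spatially correlated dynamics,
verify that counting the generated corpus reproduces the planted tensor,
compare window sizes, roll a recurrent forecast, and rank growth:

```r
library(cowordcast)

sc <- trend_scenario(k_ai = 12, k_bio = 15, bins = 12, base_rate = 8,
                     dynamics = list(type = "linear", slope = 0.08),
                     spatial_corr = 0.4, seed = 42)
gen <- generate_corpus(sc)
tok <- preprocess_corpus(gen$records, gen$merge_phrases)
tn  <- count_tensor(tok, gen$ai_order, gen$bio_order, gen$binning)
identical(tn$counts, gen$tensor$counts)
#> [1] TRUE

window_size_sweep(tn, c(1, 3), c("ridge", "elastic_net"), seed = 0)
#>       backend w mean_r2 n_bins
#> 1       ridge 1  0.1926     10
#> 2 elastic_net 1  0.0748     10
#> 3       ridge 3  0.2097     10
#> 4 elastic_net 3  0.0888     10

run <- recurrent_forecast(tn, start_bin = 9, horizon = 4, "ridge", 3, seed = 0)
round(run$r2_trace, 3)
#> 2004H1 2004H2 2005H1 2005H2
#>  0.244 -0.008 -0.014 -0.213

growth_table(tn, past_bins = 1:6, recent_bins = 7:12, threshold = 10, top_n = 5)
#> <trend_table> metric=growth, 5 row(s)
#>   rank      ai_term bio_term    value past_count recent_count
#> 1    1       aiqaal  bioqaai 118.7500         16           35
#> 2    2       aiqaak  bioqaag 117.8571         28           61
#> 3    3 aiqaaj+model  bioqaad 110.8108         37           78
#> 4    4       aiqaah  bioqaaf 106.8966         29           60
#> 5    5       aiqaad  bioqaal 102.2222         45           91
```

Reading the output: the round-trip `TRUE` confirms the document generator
and the document-level counter agree exactly. In the sweep, the 3x3 window
improves the mean `R^2` over the keyword-only baseline for both backends
(0.21 vs 0.19 for ridge; 0.089 vs 0.075 for the elastic net) — modest here
because this small world is noise-dominated (Poisson counts around
intensity 8). The recurrent trace declines with horizon, the expected decay
as predictions feed predictions. The growth table ranks pairs by
`100 * (recent - past) / past` among pairs with at least 10 past-period
co-occurrences; `aiqaaj+model` is a planted multiword keyword that survived
the surface-form merge (`aiqaaj model` -> `aiqaaj+model`).

For real data, point `run_pipeline()` (or the CLI) at a MEDLINE XML / TSV /
JSON-lines corpus plus two reference lexicons, and it runs
ingest -> embed -> vocab -> tensor -> forecast -> trends, writing every
artifact with a provenance manifest.

## Command line

```sh
CLI=$(Rscript -e 'cat(cowordcast::cowordcast_cli())')
Rscript $CLI simulate --scenario scenario.json -o corpus.tsv --truth truth
Rscript $CLI ingest -i corpus.tsv --format tabular --from 2000-01 --to 2021-12 -o corpus.jsonl
Rscript $CLI pipeline --config config.json
```

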