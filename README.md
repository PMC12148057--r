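# scadvisor

An LLM-guided workflow assistant for single-cell RNA-seq analysis, for
researchers who run the standard scRNA-seq pipeline (QC filtering →
normalization → highly variable genes → PCA → neighbor graph → clustering →
annotation → enrichment) and want data-driven parameter recommendations and
interpretations at each stage — with every LLM interaction auditable and
the whole pipeline testable offline.

## What it does

At each workflow stage, scadvisor

1. **computes data metrics** from the count matrix: QC summary statistics
   and quantiles, library-size mean/median/CV, per-PC variance-explained
   fractions, top PC-loading genes, mean expression variability over HVGs,
   the median k-nearest-neighbor distance in PC space, and top cluster
   markers;
2. **renders an augmented prompt** from an editable plain-text template,
   injecting the metrics at full precision plus your experiment
   description;
3. **dispatches** the prompt to a pluggable backend — Google
   (gemini-1.5-flash-latest), OpenAI (gpt-4o-mini), a local Ollama server
   (llama3), or a deterministic **replay** store of canned responses for
   offline use and testing;
4. **parses** the structured recommendation back into R: filtering cutoffs,
   a normalization method, a PC count, `k.param` and resolution ranges,
   per-cluster cell-type labels (optionally written back to the dataset),
   and network edges;
5. stores everything as a `RecommendationRecord` (prompt, raw response,
   parsed payload, backend identity) serialisable to JSON.

Two stages go further: `analyze_enrichment()` runs a **native
over-representation analysis** — for each gene set, the one-sided
hypergeometric tail p = P[X ≥ k] with X ~ Hypergeom(N, K, n) over a
universe of all detected genes, Benjamini–Hochberg adjusted — and feeds the
table to the LLM for an integrated summary; `summary_network()` makes a
second-round LLM call to extract `source|relation|target` edges from that
summary and writes a self-contained interactive HTML network.

For auditing, the evaluation module scores **groundedness**
G = |GT ∩ LLM| / |LLM| — the fraction of response terms present in the
data-derived ground truth, an indirect hallucination measure — and
**semantic similarity** via chunked embeddings (⌈L/(limit−2)⌉ chunks, mean
pooling, cosine), with a deterministic bag-of-words embedder built in and
the transformer embedder pluggable.

A seed-reproducible synthetic generator (negative-binomial counts,
log-normal library sizes, planted population markers) plus the replay
backend make every stage testable with no network and no real data.

## Worked example (offline)

```r
library(scadvisor)

ds  <- prepare_layers(generate_counts(synth_config(
         n_cells = 500, n_genes = 1000, n_populations = 3, seed = 1)))
backend <- make_replay_backend(build_fixture_store())

rec <- run_task("recommend_res", ds, backend)
```

The rendered prompt contains the metrics actually computed from this
dataset:

```
- Number of highly variable genes: 1000
- Mean expression variability: 2.67678598416028
- Median neighbor distance in the k-nearest-neighbor graph: 9.69011866380059
```

and the parsed payload is the recommended resolution scan:

```r
str(rec$parsed_payload[1:3])
#> List of 3
#>  $ start: num 0.2
#>  $ stop : num 1.2
#>  $ step : num 0.1
```

meaning: cluster at resolutions seq(0.2, 1.2, 0.1) and compare. Auditing
the canned replay response against this prompt's own terms:

```r
g <- groundedness(tokenize_terms(rec$rendered_prompt),
                  tokenize_terms(rec$raw_response))
#> G = 0.235 (16 of 68 response terms grounded)
```

— low, as expected: the replay fixture echoes a *different* dataset's
metrics, which is exactly what the score is designed to expose. With a live
backend the response echoes the supplied values and G approaches 1.

The same tasks are available from the command line
(`exec/scadvisor <subcommand>`; subcommands `quality`, `normalization`,
`variable-features`, `pcs-recommend`, `pcs-analyze`, `k`, `res`,
`annotate`, `enrich`, `network`, `evaluate`, `synth`), all runnable offline
with `--server replay --fixtures default`.

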