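---
title: "scadvisor: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scadvisor: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scadvisor)
```

## The assistance model

scadvisor treats each stage of the standard scRNA-seq workflow as a
*task*: a triple of (metric gatherer, prompt template, response parser).
The assistant never decides anything itself — it computes metrics that
summarize the dataset, shows them to a large language model inside a
task-specific instruction template, and parses the model's recommendation
back into a structured R object that the user can accept, edit or ignore.
The ten tasks cover QC cutoffs, normalization choice, variable-feature
interpretation, PC count, PC interpretation, `k.param` and resolution
ranges, cluster annotation, enrichment summarization, and network
extraction.

Two assumptions follow from this design. First, the LLM only sees what the
gatherer puts in the prompt, so every number in a response is auditable
against the prompt (the `echoed_numbers()` helper and the groundedness
score exist for exactly this audit). Second, recommendations are only as
reproducible as the backend: we default to temperature 0, and the replay
backend makes the whole loop deterministic for testing.

## Metric definitions and conventions

Where the workflow literature leaves a statistic underspecified we fixed
one convention, used it everywhere, and test it against independent
oracles:

* **Variance**: sample variance (ddof = 1) throughout; **quantiles**:
  linear interpolation between order statistics (R type 7). The QC grid is
  1/5/10/25/50/75/90/95/99% — a guess at a reasonable audit grid, recorded
  here because no canonical grid exists.
* **Library-size CV** = sd/mean of per-cell total counts;
  **zero fraction** = zero entries / all entries.
* **Log-normalization** (when a lognorm layer is not supplied): per-cell
  scaling to 10,000 counts then log1p — the default of the dominant
  single-cell toolkits, chosen so values are comparable with what users
  see elsewhere. Layers already present on the container are honored
  untouched, so upstream pipeline results always win.
* **Mean expression variability** is not a standard statistic; we define
  it as the mean over flagged HVGs of per-gene dispersion
  (sample variance / mean of lognorm values), genes with zero mean
  contributing 0. It is scale-free and lands in the O(1) range users see
  printed in workflow reports; it is not comparable across different
  normalizations.
* **Median neighbor distance**: the median of all cells × k Euclidean
  distances to each cell's k nearest neighbors (self excluded) in the
  first `n_pcs` PCs; k defaults to 20, `n_pcs` to 10. We use raw k-NN
  distances, not shared-nearest-neighbor similarities — the alternative
  reading — because a distance in PC space has interpretable units.
  Computation is exact: brute force under 5,000 cells, kd-tree above.
* **ORA**: p = P[X ≥ k], X ~ Hypergeom(N, K, n), with the universe
  defaulting to all genes detected in ≥ 1 cell; BH adjustment across all
  tested sets; gene matching case-insensitive (human/mouse symbol
  conventions differ in case only). Ranked GSEA is deliberately out of
  scope.

## Prompt engine

Templates are plain-text package resources, one per task, with
single-brace `{placeholder}` syntax and a doubling escape (`{{` → `{`).
Substituted values are inserted literally and never re-scanned, so a
response or metric containing brace characters cannot inject placeholders.
Numbers are rendered at 15 significant digits — the model should see
exactly what was computed. A user-supplied template directory overrides
any packaged template of the same name. The experiment description is
optional; its placeholder resolves to a fixed "No experiment description
was provided." sentence rather than silently vanishing, so its absence is
visible in the audit trail. Our templates are zero-shot instructions; we
do not attempt few-shot examples or prompt optimization.

## Backends and the replay store

Remote contracts (Google, OpenAI, Ollama) are built by pure functions and
dispatched with 3 attempts and exponential backoff on 5xx/timeouts; 4xx
fails fast, and authentication errors never echo the key. Timeout and
retry policy are our engineering choices — no published values exist for
this. The **replay** backend maps (task id, prompt fingerprint) to stored
text with a per-task default fallback; it is the only backend the test
suite uses, so the suite performs no network I/O anywhere.

## Parsers

Parsers are intentionally forgiving in dialect but strict in semantics:

* resolution ranges accept `seq(a, b, s)` or "a to b … steps of s";
* cutoffs bind each number to the nearest preceding metric mention, with
  direction words choosing the side; the *first* bound per metric/side
  wins, because models habitually re-mention the same numbers inside
  their reasoning in the opposite direction;
* annotations require one `Cluster <id>: <label>` line per requested
  cluster — unknown clusters are warned and ignored, missing clusters are
  an error, and dataset write-back is atomic (a parse failure writes
  nothing);
* network extraction imposes a `source|relation|target` wire format via
  the prompt; malformed lines are skipped with a warning, duplicates and
  self-loops dropped, and zero edges is an error that preserves the raw
  text.

A failed parse never loses information: `run_task()` returns the record
flagged unparsed with the raw response intact.

## Evaluation statistics

Groundedness is G = |GT ∩ LLM| / |LLM| on normalized token sets:
case-folded, split on non-alphanumerics with `-` and `_` kept inside
tokens (so NF-kB survives), stopwords and single characters dropped. We
score single tokens, not multi-word terms — a choice, recorded here, since
the upstream procedure's tokenization was never specified. G is monotone:
growing the ground truth cannot lower it; adding ungrounded response
terms cannot raise it.

Semantic similarity chunks a document into ⌈L/(limit−2)⌉ non-overlapping
token chunks (two slots reserved for a transformer's boundary markers),
embeds each chunk, mean-pools (the conventional reading of "combined"),
and takes the cosine. The embedder is a pluggable
`function(tokens) -> vector`; the package ships a deterministic
bag-of-words embedder over a fixed vocabulary so all of this is exactly
testable offline. The published BERT-based scores (~0.74–0.76) depend on
model weights and live responses and are therefore not reproduced here;
what our tests establish is the *machinery* — chunk arithmetic, pooling,
cosine identities — not those numbers.

## The synthetic world

`generate_counts()` draws negative-binomial counts (size 2) with
per-gene gamma baseline means, log-normal library factors (sdlog 0.35),
and per-population marker genes up-regulated 8-fold — by default 500
cells × 1,000 genes × 3 populations, the scale used by the end-to-end
determinism criterion. This emulates what the metric and ORA code paths
need (overdispersion, library-size spread, planted signal with known
truth) and nothing more: no doublets, ambient RNA, batch effects or
dropout beyond NB sampling. A green test therefore establishes numerical
correctness and pipeline determinism, not biological realism of any
recommendation.

## Degenerate inputs and tie-breaks

All-zero matrices are rejected at normalization ("nothing to normalize");
zero-mean genes contribute 0 dispersion; PC-loading and marker ties break
by gene-name lexicographic order so outputs are stable across platforms;
cluster ids are strings throughout ("0", "1", …) to match marker-table
conventions; percent-type QC columns are validated to [0, 100] —
percentages, not fractions, which the prompt templates state implicitly
by example.

## Known limitations

Live-backend behavior (drift, refusals, rate limits) is untested by
design. The cutoff parser's nearest-preceding-mention heuristic can
mis-bind numbers in convoluted prose; the record keeps the raw text so
nothing is lost. H5AD support covers dense and CSR/CSC `X` and named
layers, not backed/chunked encodings. The bag-of-words embedder is a test
double: its similarity values are not comparable to transformer-based
ones.
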