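Package: scadvisor
Title: LLM-Guided Workflow Assistant for Single-Cell RNA-Seq Analysis
Version: 0.1.0
Authors@R:
    person("scadvisor", "maintainers", email = "scadvisor@example.org",
           role = c("aut", "cre"))
Description: A workflow assistant for single-cell RNA-seq analysis that
    computes stage-specific data metrics (quality control summaries,
    library-size statistics, variance explained by principal components,
    expression variability, neighbor-graph distances, cluster markers),
    renders them into augmented prompt templates, dispatches the prompts to
    a pluggable large-language-model backend (Google, OpenAI, Ollama, or a
    deterministic offline replay store), and parses the structured
    recommendations back into R objects: filtering cutoffs, normalization
    choices, principal-component counts, neighbor and resolution parameter
    ranges, cell-type annotations, and a native hypergeometric
    over-representation analysis with a network summary. Also implements
    groundedness scoring and chunked-embedding semantic similarity for
    auditing LLM responses against data-derived ground truth, and a
    seed-reproducible negative-binomial synthetic data generator so the
    entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    digest,
    FNN,
    igraph
Suggests:
    testthat (>= 3.0.0),
    httr,
    rhdf5
Config/testthat/edition: 3
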