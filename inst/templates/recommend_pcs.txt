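You are choosing the dimensionality for a single-cell RNA-seq analysis.

Experiment context: {experiment_description}

Variance explained by each principal component (fraction of total, with the
cumulative fraction alongside):

{variance_table}

Recommend the optimal number of principal components to keep for downstream
neighbor-graph construction and clustering. State it as "Recommended number
of PCs: <integer>", then justify it from the variance profile (for example
an elbow or a cumulative-variance argument).
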