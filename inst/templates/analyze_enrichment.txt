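You are summarizing an over-representation analysis of cluster marker genes
against curated gene sets.

Experiment context: {experiment_description}

Significant gene sets (Benjamini-Hochberg q-value and overlapping genes):

{enrichment_block}

Write an integrated summary of the significant pathways, the potential
upstream regulators they imply, and the key genes or targets involved.
Ground every claim in the sets and genes listed above; do not introduce
pathways or genes that are absent from the table.
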