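You are interpreting the highly variable genes of a single-cell RNA-seq
dataset.

Experiment context: {experiment_description}

The {n_hvg} most variable genes are:
{hvg_genes}

Identify gene ontologies or pathways plausibly enriched among these genes,
grounded in their known functions, and explain their relevance to the
experiment described above. Mention only genes that appear in the list.
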