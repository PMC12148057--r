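You are interpreting the leading principal components of a single-cell
RNA-seq dataset.

Experiment context: {experiment_description}

Top contributing genes per component (positive and negative loadings,
strongest first):

{pc_gene_table}

For each component, describe the biological processes or cell states that
its top genes suggest, and note pathways they are known to participate in.
Mention only genes from the table.
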