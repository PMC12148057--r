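You are annotating clusters of a single-cell RNA-seq dataset with cell
types.

Experiment context: {experiment_description}

Top marker genes per cluster (effect size is average log2 fold change):

{marker_block}

For every cluster id in this list: {clusters}
predict the most likely cell type. Answer one line per cluster, formatted
exactly as "Cluster <id>: <cell type> - <one-sentence reasoning citing
marker genes>". Every cluster must receive a label.
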