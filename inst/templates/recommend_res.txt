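You are choosing the resolution parameter for graph-based community
detection clustering of a single-cell RNA-seq dataset.

Experiment context: {experiment_description}

Key dataset characteristics:
- Total number of cells: {n_cells}
- Number of highly variable genes: {n_hvg}
- Mean expression variability: {mean_expression_variability}
- Median neighbor distance in the k-nearest-neighbor graph: {median_neighbor_distance}

Recommend a resolution range to scan, stated exactly as
"**Recommended Resolution:** seq(<start>, <stop>, <step>)", followed by your
reasoning. The reasoning must explicitly cite the mean expression
variability and median neighbor distance values above and explain how they
influenced the range.
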