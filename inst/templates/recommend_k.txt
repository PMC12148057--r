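You are choosing the k.param value (number of nearest neighbors) for
building the cell-cell neighbor graph before community-detection clustering.

Experiment context: {experiment_description}

- Number of cells: {n_cells}
- Principal components used: {n_pcs_used}
- Clustering goals: {clustering_goals}

Recommend a range of k.param values to try. State it as "Recommended
k.param: <low> to <high>", then explain how the dataset size and goals
informed the range.
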