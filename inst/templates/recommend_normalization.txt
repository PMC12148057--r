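You are assisting with normalization of a single-cell RNA-seq dataset.

Experiment context: {experiment_description}

Dataset characteristics:
- Number of cells: {n_cells}
- Library size: mean {libsize_mean}, median {libsize_median}, coefficient of variation {libsize_cv}
- Fraction of zero entries in the count matrix: {zero_fraction}
- Per-gene mean expression quantiles (10/25/50/75/90%): {gene_mean_quantiles}

Choose the most suitable normalization method from this menu: {method_menu}.
Name the chosen method on its own line as "Recommended method: <name>", then
explain your reasoning, citing the library size variation and expression
distribution above.
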