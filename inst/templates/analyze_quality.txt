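You are assisting with quality control of a single-cell RNA-seq dataset.

Experiment context: {experiment_description}

The dataset contains {n_cells} cells. Summary statistics and quantiles for
each quality metric are given below (quantiles at 1, 5, 10, 25, 50, 75, 90,
95 and 99 percent):

{qc_stats_block}

Based on these distributions, recommend lower and/or upper filtering cutoffs
for each metric. State each cutoff as an explicit number next to the metric
name (for example "nFeature_RNA > 200 and < 5000", "percent_mito below 10").
Then explain your reasoning, explicitly citing the metric values above that
drove each choice.
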