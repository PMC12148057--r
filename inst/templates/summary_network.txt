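Extract a directed network from the enrichment summary below. Output ONLY
edge lines, one per line, formatted exactly as

source|relation|target

where source and target are pathway, regulator or gene names from the
summary and relation is a short verb phrase (e.g. activates, regulates,
member_of). No other text.

Summary:
{summary_text}
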