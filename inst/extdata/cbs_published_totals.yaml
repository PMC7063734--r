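# Headline counts of the splenic B-cell subset survey: 182,783 productive
# unique IGHV1 sequences collapsed into 117,027 clonal families, of which
# 279 matched a major CLL stereotyped subset (0.24%).
total_sequences: 182783
total_clones: 117027
cbs_clones: 279
printed_cbs_percent: 0.24
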