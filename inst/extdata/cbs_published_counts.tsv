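subset_id	clones	printed_percent	printed_decimals
#12	142	0.12	2
#28A	57	0.048	3
#7H	21	0.018	3
#3	23	0.019	3
#5	17	0.014	3
#6	10	0.009	3
#1-99	6	0.005	3
#59	3	NA	NA
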