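set	novel_genes	annotation_extensions	noncoding_overlaps	primers_tested
preliminary	1	0	2	6
set1	3	1	0	30
set2	0	2	0	12
set3	2	1	0	96
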