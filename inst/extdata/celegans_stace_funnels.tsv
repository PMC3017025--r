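set	total_tags	mappable_tags	non_transcriptome_tags	frequency_tags	position_tags	gc_tags	primer_ready_tags	primers_tested
set1	16587	13743	3052	616	418	128	39	30
set2	14701	10534	4755	365	41	19	12	12
set3	359457	32416	13542	8211	469	124	106	96
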