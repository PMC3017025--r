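result	label	primer	tag_chrom	tag_pos	bound5_chrom	bound5_pos	bound3_chrom	bound3_pos	sl1_evidence	polya_evidence	genbank	note
P.1	full_length	GTTAGGATCGTAGAGGACATG	II	8786920	II	8786297	II	8787044	TRUE	TRUE	HQ451870	overlaps F07H5.4 (pseudogene); extension to annotated exon
P.2	partial	AGAGGATTAATTCCCCCCATG	II	9375813	II	9376228	II	9375792	TRUE	FALSE	HQ451877	overlaps C06C3.10
P.3	full_length	GGGGGAAAATCGAAAGACATG	II	10201160	II	10202155	II	10201084	TRUE	TRUE	HQ451871	overlaps tts-2 (ncRNA); new intron
1.1	partial	GAAACGAAGAAGAAAAGCATG	V	19434698	V	19434352	V	19434718	TRUE	FALSE	HQ451878	novel gene
1.2	full_length	TTCGACGGCAGATTGTTCATG	V	19432707	V	19433037	V	19432406	TRUE	TRUE	HQ451872	overlaps C25F9.11; new 5' UTR
1.3	full_length	TAGCTCAGTCAAAACAACATG	V	5812559	V	5813070	V	5812296	TRUE	TRUE	HQ451873	overlaps ZC250.4; extension to 3' UTR
1.4a	partial	AAAGTTGAGCTTCTGCTCATG	X	2346863	X	2335678	X	2346883	TRUE	FALSE	HQ451879	overlaps T01B6.1; new coding sequence
1.4b	partial	AAAGTTGAGCTTCTGCTCATG	X	2346863	X	2345479	X	2346883	TRUE	FALSE	HQ451880	overlaps T01B6.1; new transcriptional start site
2.1a	partial	TGGTTGTTAGTAGTGTACATG	II	15229391	II	15207408	II	15229412	TRUE	FALSE	HQ451881	overlaps Y46E12BL.4; new 3' UTR exon
2.1b	partial	TGGTTGTTAGTAGTGTACATG	II	15229391	II	15216289	II	15229412	TRUE	FALSE	HQ451882	overlaps Y46E12BL.4; new initial coding exon
2.2	full_length	CCATCTAAAGGGCTCTACA	IV	4415359	IV	NA	IV	4415616	TRUE	TRUE	HQ451874	overlaps Y24D9A.1; extension to 3' UTR; printed 5' boundary (44085996) is a typographical artifact, stored as NA
3.1	full_length	CTCATTGAAGGTGAAGCAT	X	14690913	X	14692920	X	14690763	TRUE	TRUE	HQ451875	overlaps sox-3; new 3' UTR
3.2	partial	TGAAATGTCACAGTACACAT	III	7604002	III	7601399	III	7604022	TRUE	FALSE	HQ451883	novel gene
3.3	full_length	GAGAGAATTGTTGTGACCAT	X	4681136	X	4682689	X	4680952	TRUE	TRUE	HQ451876	novel gene
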