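name	forward	reverse	max_mismatches	min_product	max_product
515F_806R	GTGYCAGCMGCCGCGGTAA	GGACTACNVGGGTWTCTAAT	0	200	500
27F_1492R	AGAGTTTGATCMTGGCTCAG	TACGGYTACCTTGTTACGACTT	0	1200	1600
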