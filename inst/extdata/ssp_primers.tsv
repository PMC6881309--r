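id	sequence	orientation	target_note	nested_parent	printed_tm_c	printed_gc_pct	printed_lc_pct
5315	CTSAAGCGGATCGAGAACAAGATCAACC	F	exon1	NA	61.5	50.0	78
5410	CTCATCATCTTCTCCACCAAGGGAAAGCTCTACGAGTTC	F	exon1	NA	66.2	48.7	81
5299	GTTCTCGATCCGCTTSAGCTGCACCTT	R	exon1	NA	64.5	55.6	89
5411	GCACGGAGATCTCGTGCGCCTTCTTGAG	R	exon1	NA	66.8	60.7	89
5412	CTCGTAGAGCTTTCCCTTGGTGGAGAAGATGATGAG	R	exon1	NA	65.3	50.0	80
5317	ARCGGTAYGAGCGYTACTCYTATGCAGA	F	exon2	NA	62.3	50.0	87
5413	GARCGGTATGAGCGCTAYTCYTATGCAGA	F	exon2	NA	62.4	50.0	83
5300	TARGAGTARCGCTCRTACCGYTCAAGAA	R	exon2	NA	60.5	46.4	83
5301	GTARCGCTCRTACCGYTCAAGAATTTTGTCCATA	R	exon2	NA	62.8	42.6	88
5416	CAGCCGTTGATGTGGCTCACCATCCA	R	exon8	NA	64.7	57.7	93
5445	CTTGTTTTGGGCCGTCTCGCTTC	R	promoter	NA	61.2	56.5	73
5446	CGTCTCGCTTCTCCCGTTTGGGCAT	R	promoter	5445	64.9	60.0	81
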