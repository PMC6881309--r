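id	sequence	printed_tm_c	printed_gc_pct	printed_lc_pct
5600	GTTGCGGCAGGTCCTCACC	69.1	68.1	89
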