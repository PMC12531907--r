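chr11	47380150	47380175	GATA1_SPI1_upstream
chr19	44809000	44809020	GATA1_BCAM_intron
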