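chr22	42721255	42721280	STAT1_A4GALT_5UTR
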