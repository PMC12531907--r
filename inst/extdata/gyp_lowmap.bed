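chr4	143820800	143822400	lowmap_1
chr4	143860800	143864000	lowmap_2
chr4	143912000	143913600	lowmap_3
chr4	143968000	143971200	lowmap_4
chr4	144056000	144057600	lowmap_5
chr4	144120000	144121600	lowmap_6
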