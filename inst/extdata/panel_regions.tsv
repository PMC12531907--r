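name	chrom	start	end	role
rhd_locus	chr1	25272392	25330445	locus
rhce_locus	chr1	25360658	25430193	locus
rhd_ex2	chr1	25283000	25291000	tract
rhce_ex2	chr1	25402000	25410000	tract
gyp_region	chr4	143778400	144141600	hmm
gype	chr4	143780000	143812000	gene
gypb	chr4	143997600	144008800	gene
gypa	chr4	144109600	144140000	gene
gypb_del_span	chr4	143996000	144010400	event
dantu_template	chr4	144000800	144108000	event
gyp_diploid_flank	chr4	143813600	143994400	flank
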