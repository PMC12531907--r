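id	system	chrom	pos	ref	alt	cdna	protein	class
rs8176719	ABO	chr9	133257521	T	TG	c.261del	p.Thr88ProfsTer31	indel
rs8176746	ABO	chr9	133255928	C	A	c.796C>A	p.Leu266Met	snv
rs8176747	ABO	chr9	133255935	G	A	c.803G>A	p.Gly268Ala	snv
rhd_del	Rh	chr1	25272393	N	<DEL>	RHD*01N.01	whole-gene deletion	structural-tag
rs748783394	Rh	chr1	25293000	A	ATGCCCTGAGATGGCTGTCACCACGCTGACTGCTAGAC	c.487dup37	p.Thr163fs	indel
rhce_conv	Rh	chr1	25405000	N	<CONV>	RHCE exon 2 conversion	RHCE*C exon-2 hybrid	structural-tag
rs609320	Rh	chr1	25390874	G	C	c.676G>C	p.Ala226Pro	snv
rs141398055	Rh	chr1	25397810	G	C	c.602G>C	p.Arg201Thr	snv
rs8176058	Kell	chr7	142922939	C	T	c.578C>T	p.Thr193Met	snv
rs8176059	Kell	chr7	142921634	C	T	c.841C>T	p.Arg281Trp	snv
rs1058396	Kidd	chr18	43319519	G	A	c.838G>A	p.Asp280Asn	snv
rs12075	Duffy	chr1	159205564	G	A	c.125G>A	p.Gly42Asp	snv
rs2814778	Duffy	chr1	159204893	T	C	c.-67T>C		snv
rs34599082	Duffy	chr1	159205704	C	T	c.265T>C	p.Arg89Cys	snv
rs773692057	Duffy	chr1	159205617	CCT	C	c.179_180del	p.Ser62CysfsTer16	indel
rs601338	Lewis	chr19	48703417	G	A	c.461G>A	p.Trp154Ter	snv
rs28362459	Lewis	chr19	5844784	T	G	c.59T>G	p.Leu20Arg	snv
rs812936	Lewis	chr19	5844641	T	C	c.202T>C	p.Trp68Arg	snv
rs778986	Lewis	chr19	5844529	C	T	c.314C>T	p.Thr105Met	snv
rs3894326	Lewis	chr19	5843776	T	A	c.1067T>A	p.Ile356Lys	snv
rs28399653	Lutheran	chr19	44812188	G	A	c.230G>A	p.Arg77His	snv
rs7682260	MNS	chr4	144140723	C	T	c.59C>T	p.Ser20Leu	snv
rs7687256	MNS	chr4	144140711	G	A	c.71G>A	p.Gly24Glu	snv
rs7658293	MNS	chr4	144140710	T	G	c.72T>G	p.Gly24Glu	snv
rs7683365	MNS	chr4	144001261	C	T	c.143C>T	p.Thr48Met	snv
rs139511876	MNS	chr4	143999443	G	T	c.270+5G>T		snv
gypb_del	MNS	chr4	143996800	N	<DEL>	GYPB*05N.01	whole-gene deletion	structural-tag
dantu	MNS	chr4	144001000	N	<DUP>	GYP.Dantu	GYPB-GYPA hybrid duplication	structural-tag
rs5751348	P1	chr22	42696035	G	T	c.-188+3010G>T		snv
rs8138197	P1	chr22	42696793	C	T	c.-188+2252C>T		snv
rs2143918	P1	chr22	42696262	T	G	c.-188+2783T>G		snv
rs66781836	P1	chr22	42695745	CT	C	c.-188+3300del		indel
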