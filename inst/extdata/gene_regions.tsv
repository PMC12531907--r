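gene	system	chrom	start	end
ABO	ABO	chr9	133250000	133280000
RHD	Rh	chr1	25272392	25330445
RHCE	Rh	chr1	25360658	25430193
KEL	Kell	chr7	142914000	142936000
SLC14A1	Kidd	chr18	43310000	43330000
ACKR1	Duffy	chr1	159203000	159207000
FUT2	Lewis	chr19	48695000	48706000
FUT3	Lewis	chr19	5842000	5852000
BCAM	Lutheran	chr19	44806000	44820000
SPI1	Lutheran	chr11	47354000	47382000
GYPE	MNS	chr4	143780800	143812800
GYPB	MNS	chr4	143995200	144009600
GYPA	MNS	chr4	144108800	144140800
A4GALT	P1	chr22	42692000	42722300
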