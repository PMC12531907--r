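gene	chrom	start	end
ABO	chr9	133255601	133258000
FUT2	chr19	48702926	48703991
FUT3	chr19	5843500	5844850
BCAM	chr19	44810000	44815000
A4GALT	chr22	42692115	42692600
GYPA	chr4	144138000	144140900
GYPB	chr4	143999000	144002000
KEL	chr7	142918000	142935000
SLC14A1	chr18	43315000	43325000
ACKR1	chr1	159204800	159206000
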