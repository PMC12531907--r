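allele	system	requires	effects
ABO*A1.01	ABO	rs8176719=alt	A=express
ABO*B.01	ABO	rs8176719=alt;rs8176746=alt;rs8176747=alt	B=express
ABO*O.01.01	ABO	rs8176719=ref	A=silence;B=silence
RHD*01	Rh	rs748783394=ref	D=express
RHD*01N.01	Rh	rhd_del=alt	D=silence
RHD*08N.01	Rh	rs748783394=alt	D=silence
RHCE*Ce	Rh	rhce_conv=alt	C=express;c=silence
RHCE*ce	Rh	rhce_conv=ref;rs609320=ref	c=express;e=express
RHCE*cE	Rh	rs609320=alt	E=express;e=silence
RHCE*ce.02	Rh	rs141398055=alt	E=weaken
KEL*01.01	Kell	rs8176058=alt	K=express;k=silence
KEL*02	Kell	rs8176058=ref	k=express;Kpb=express
KEL*02.03	Kell	rs8176059=alt	Kpa=express;Kpb=silence
JK*01	Kidd	rs1058396=ref	Jka=express
JK*02	Kidd	rs1058396=alt	Jkb=express
FY*01	Duffy	rs12075=ref	Fya=express
FY*02	Duffy	rs12075=alt	Fyb=express
FY*02N.01	Duffy	rs12075=alt;rs2814778=alt	Fya=silence;Fyb=silence
FY*02W.01	Duffy	rs12075=alt;rs34599082=alt	Fyb=weaken
FY*01N.06	Duffy	rs773692057=alt	Fya=silence;Fyb=silence
LE*01	Lewis	rs812936=ref;rs778986=ref	Lea=express;Leb=express
LE*01N.03	Lewis	rs812936=alt;rs778986=alt	Lea=silence;Leb=silence
LE*01N.09	Lewis	rs28362459=alt;rs3894326=alt	Lea=silence;Leb=silence
SE*01	Lewis	rs601338=ref	Leb=express
SE*01N.02	Lewis	rs601338=alt	Leb=silence;Lea=express
LU*01	Lutheran	rs28399653=alt	Lua=express;Lub=silence
LU*02	Lutheran	rs28399653=ref	Lub=express
GYPA*M	MNS	rs7682260=alt;rs7687256=alt;rs7658293=alt	M=express;N=silence
GYPA*N	MNS	rs7682260=ref	N=express
GYPB*S	MNS	rs7683365=alt	S=express;s=silence
GYPB*s	MNS	rs7683365=ref	s=express
GYP.He(P2)	MNS	rs139511876=alt	S=silence;s=silence
GYPB*05N.01	MNS	gypb_del=alt	S=silence;s=silence
GYP.Dantu	MNS	dantu=alt	s=weaken
P1PK*P1	P1	rs5751348=ref	P1=express
P1PK*P2	P1	rs5751348=alt;rs8138197=alt;rs2143918=alt	P1=silence
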