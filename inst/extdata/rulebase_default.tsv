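# Default transport rulebase (v1). One rule per residue-signature class.
# constraints: comma-separated <position>=<letters>; bracket sets allowed,
# e.g. H2=[AG]. Positions: LB, LE, H2, H5, LE1, LE2, P1..P5 (LB/LE match the
# full 3-letter loop motif). subfamily matches by prefix (PIP matches PIP1
# and PIP2). substrates and codes are ;-separated and aligned pairwise.
# Evidence codes follow the literature-synthesis convention: a Azad 2016,
# b Hove & Bhave 2011, c Perez Di Giorgio 2014, d Dynowski 2008,
# e Wallace 2004, f Wallace & Roberts 2005, g Azad 2011, h Kirscht 2016,
# i Deshmukh 2015, j Jahn 2004, k Mitani-Ueno 2011; *1/*2/*3 orthology-based
# (maize / arabidopsis / rice).
rule_id	subfamily	constraints	substrates	codes	source
pip_co2	PIP	H2=F,H5=H,LE1=T,LE2=R	CO2	ab	homology
pip_h2o2	PIP	H2=F,H5=H,LE1=T,LE2=R	H2O2	ac	homology
pip1_boron	PIP1	P1=Q	B	*1	ZmPIP1 orthologues
pip1_urea	PIP1	P1=E	urea	*1	ZmPIP1;5 orthologue
pip2_arsenic	PIP2	H2=F,H5=H,P1=M	As	c*3	OsPIP2;6 orthologue
tip1_set	TIP	H5=I,LE2=V	H2O2;NH3;urea;B	*2;j*2;b*2;*1	AtTIP1/ZmTIP1
tip1_glycerol	TIP	H5=I,LE2=V,P2=T	Gly	*3	OsTIP1;2 orthologue
tip2_set	TIP	H5=I,LE1=G,LE2=R	H2O2;NH3;urea	ac;abcghj;abcdg	AtTIP2 + mutagenesis
tip_nh3_urea	TIP	H2=H,LE1=A,LE2=R	NH3;urea	gj;bd	ar/R mutagenesis
tip4_h2o2	TIP	H2=H,H5=I,LE1=A,LE2=R,P3=A	H2O2	a	AtTIP4;1 orthologue
tip5_urea	TIP	H2=N	urea	d	AtTIP5;1 orthologue
nip1_glycerol	NIP	H2=W,H5=V,LE1=A,LE2=R	Gly	e	NIP group I ar/R
nip1_set	NIP	H2=W,H5=V,P1=F	H2O2;As;Sb;B	a*1*2;c*2*3;*2;*1	AtNIP1/ZmNIP1;1
nip2_silicon	NIP	H2=G,H5=S	Si;H2O2;As;Sb;urea;B;Gly	abik*1*3;*1;ac*1*3;ak*1*3;abc*3;bck*1*3;c*1	NIP group III
nip2b_metalloid	NIP	H2=C	Si;As;B	k;k;k	OsNIP2;1 H2 mutagenesis
nip5_set	NIP	H2=A,H5=I	As;Sb;B;urea;Gly	ack*2;a*2;ack*2;f;cf	AtNIP5;1/AtNIP6;1
nip7_set	NIP	H2=A,H5=V	urea;Gly	f;f	AtNIP7;1 + point mutations
nip6_antimonite	NIP	H2=T	Sb	a	AtNIP6;1 orthologue
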