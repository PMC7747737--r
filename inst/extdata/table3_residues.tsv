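gene_name	npa_lb	npa_le	h2	h5	le1	le2	p1	p2	p3	p4	p5	transport
CmPIP1;1	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:abc;H2O2:ab;B:*1
CmPIP1;2	NPA	NPA	F	H	T	R	E	S	A	F	W	CO2:b*2;H2O2:b;urea:*1
CmPIP2;1	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:ac
CmPIP2;2	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:ac
CmPIP2;3	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:ac
CmPIP2;4	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:ac
CmPIP2;5	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:a
CmPIP2;6	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:a
CmPIP2;7	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:a
CmPIP2;8	NPA	NPA	F	H	T	R	Q	S	A	F	W	CO2:ab;H2O2:a
CmPIP2;9	NPA	NPA	F	N	A	R	K	S	A	F	W	-
CmPIP2;10	NPA	NPA	F	H	T	R	M	S	A	F	W	CO2:abc;H2O2:*2;As:c*3
CmTIP1;1	NPA	NPA	H	I	A	V	T	A	S	Y	W	H2O2:*2;NH3:j*2;urea:b*2;B:*1
CmTIP1;2	NPA	NPA	H	I	A	V	I	A	A	Y	W	H2O2:*2;NH3:j*2;urea:b*2;B:*1
CmTIP1;3	NPA	NPA	H	I	A	V	T	T	A	Y	W	H2O2:*2;NH3:j*2;urea:b*2;B:*1;Gly:*3
CmTIP2;1	NPA	NPA	H	I	G	R	T	S	A	Y	W	H2O2:ac;NH3:abcghj;urea:abcdg
CmTIP2;2	NPA	NPA	H	I	G	R	T	S	A	Y	W	H2O2:ac;NH3:abcghj;urea:abcdg
CmTIP3;1	NPA	NPA	H	I	A	R	T	A	S	Y	W	NH3:gj;urea:bd
CmTIP4;1	NPA	NPA	H	I	A	R	T	S	A	Y	W	H2O2:a;NH3:ahj;urea:abd*2
CmTIP5;1	NPA	NPA	N	V	G	C	I	A	A	Y	W	urea:d
CmNIP1;1	NPA	NPA	W	V	A	R	F	S	A	Y	I	H2O2:a*1*2;As:c*2*3;Sb:*2;B:*1;Gly:ce*1*2
CmNIP2;1	NPA	NPV	G	S	G	R	L	T	A	Y	F	Si:abik*1*3;H2O2:*1;As:ac*1*3;Sb:ak*1*3;urea:abc*3;B:bck*1*3;Gly:c*1
CmNIP2;2	NPA	NPA	C	S	G	R	L	S	A	Y	M	Si:k;As:k;B:k
CmNIP4;1	NPA	NPA	W	V	A	R	L	T	A	Y	I	Gly:e
CmNIP5;1	NPS	NPV	A	I	G	R	F	T	A	Y	L	As:ack*2;Sb:a*2;B:ack*2;urea:f;Gly:cf
CmNIP5;2	NPS	NPV	S	I	G	R	F	T	A	Y	L	-
CmNIP6;1	NPA	NPV	T	V	A	R	F	T	A	Y	L	Sb:a
CmNIP7;1	NPA	NPA	A	V	A	R	F	S	A	Y	I	urea:f;Gly:f
CmSIP1;1	NPT	NPA	F	I	P	N	M	A	A	Y	W	-
CmSIP2;1	NPL	NPA	I	H	G	S	F	V	A	Y	W	-
CmXIP1;1	SPI	SPA	I	I	V	R	M	C	A	F	W	-
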