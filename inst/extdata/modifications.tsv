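name	motif	action	enzymes
aromatic-hydroxylation	c1ccccc1	attach O@1	Ox
phenol-O-methylation	Oc1ccccc1	attach C@1	MT
amide-N-methylation	C(=O)N	attach C@3	MT
amide-N-hydroxylation	C(=O)N	attach O@3	Ox
alcohol-O-methylation	OCC	attach C@1	MT
carboxyl-O-methylation	OC(=O)C	attach C@1	MT
keto-reduction	CC(=O)C	order 2-3=1	KR
alcohol-dehydration	CC(O)C	order 1-2=2; remove @3	DH
alkene-epoxidation	C=C	bridge O@1-2; order 1-2=1	Ox
alkene-reduction	C=C	order 1-2=1	ER
thiol-methylation	CS	attach C@2	MT
terminal-amine-methylation	NCC(=O)O	attach C@1:1	MT,Ox
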