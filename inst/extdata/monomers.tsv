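name	smiles	class	enzymes
glycine	NCC(=O)O	amino	
alanine	CC(N)C(=O)O	amino	
valine	CC(C)C(N)C(=O)O	amino	
leucine	CC(C)CC(N)C(=O)O	amino	
isoleucine	CCC(C)C(N)C(=O)O	amino	
proline	OC(=O)C1CCCN1	amino	
phenylalanine	NC(Cc1ccccc1)C(=O)O	amino	
tyrosine	NC(Cc1ccc(O)cc1)C(=O)O	amino	
tryptophan	NC(Cc1c[nH]c2ccccc12)C(=O)O	amino	
serine	NC(CO)C(=O)O	amino	
threonine	CC(O)C(N)C(=O)O	amino	
cysteine	NC(CS)C(=O)O	amino	
methionine	CSCCC(N)C(=O)O	amino	
asparagine	NC(=O)CC(N)C(=O)O	amino	
glutamine	NC(=O)CCC(N)C(=O)O	amino	
aspartate	NC(CC(=O)O)C(=O)O	amino	
glutamate	NC(CCC(=O)O)C(=O)O	amino	
lysine	NCCCCC(N)C(=O)O	amino	
arginine	NC(CCCNC(=N)N)C(=O)O	amino	
histidine	NC(Cc1c[nH]cn1)C(=O)O	amino	
lactate	CC(O)C(=O)O	hydroxy	
glycolate	OCC(=O)O	hydroxy	
2-hydroxyisovalerate	CC(C)C(O)C(=O)O	hydroxy	
malonyl	OC(=O)CC(=O)O	ketide	
methylmalonyl	CC(C(=O)O)C(=O)O	ketide	
N5-hydroxyornithine	NC(CCCNO)C(=O)O	amino	Ox
3-methylglutamate	NC(C(C)CC(=O)O)C(=O)O	amino	MT,Ox
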