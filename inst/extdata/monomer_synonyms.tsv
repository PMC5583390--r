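raw	canonical
ornithine	orn
serine	ser
threonine	thr
glycine	gly
arginine	arg
aspartate	asp
aspartic-acid	asp
glutamate	glu
glutamic-acid	glu
alanine	ala
valine	val
leucine	leu
isoleucine	ile
proline	pro
lysine	lys
cysteine	cys
methionine	met
glutamine	gln
phenylalanine	phe
tryptophan	trp
tyrosine	tyr
histidine	his
asparagine	asn
2,4-diaminobutyrate	dab
2,4-diaminobutyric-acid	dab
dhpg	hpg
hydroxyphenylglycine	hpg
malonyl-coa	mal
methylmalonyl-coa	mmal
hydroxymalonyl-coa	ohmal
ethylmalonyl-coa	emal
methoxymalonyl-coa	mxmal
x	nrp
unknown	nrp
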