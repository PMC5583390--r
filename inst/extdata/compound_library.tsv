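name	mibig_id	backbone	citation
Delftibactin	BGC0000984	pk(NH2+ohmal),Asp,Thr,Gly,Thr(mod),Orn(mod),Ser,Arg,Orn(cyclic)	Delftibactin A, metallophore of Delftia acidovorans associated with gold biomineralization
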