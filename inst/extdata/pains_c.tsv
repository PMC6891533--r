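# PAINS catalog C (representative subset)
# rule_id	smarts	category
alkylidene_thiazolidinedione	S1C(=O)NC(=O)C1=C	thiazolidinedione
hydroquinone	[OX2H]c1ccc([OX2H])cc1	hydroquinone
aromatic_nitroso	c[NX2]=O	nitroso
polyene	C=CC=CC=C	polyene
maleimide	O=C1C=CC(=O)N1	imide
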