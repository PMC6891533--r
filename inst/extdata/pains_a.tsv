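# PAINS catalog A (representative subset of published pan-assay
# interference substructure classes; drop in a full catalog to replace)
# rule_id	smarts	category
rhodanine_core	S1C(=S)NC(=O)C1	rhodanine
ene_rhodanine	S1C(=S)NC(=O)C1=C	rhodanine
catechol	[OX2H]c1ccccc1[OX2H]	catechol
quinone_para	O=C1C=CC(=O)C=C1	quinone
azo_aromatic	cN=Nc	azo
hydroxyphenyl_hydrazone	[OX2H]c1ccccc1C=NN	hydrazone
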