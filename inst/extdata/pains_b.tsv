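# PAINS catalog B (representative subset)
# rule_id	smarts	category
alkylidene_barbiturate	O=C1NC(=O)NC(=O)C1=C	barbiturate
quinone_ortho	O=C1C(=O)C=CC=C1	quinone
phenol_schiff	[OX2H]c1ccccc1C=N	imine
thiourea_acyclic	NC(=S)N	thiourea
ene_one_ene	C=CC(=O)C=C	cross_conjugated_enone
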