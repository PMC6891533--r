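# Medicinal-chemistry structural alerts (representative self-curated
# subset, binary reject; categories follow common alert taxonomy)
# rule_id	smarts	category
acyl_halide	[CX3](=O)[F,Cl,Br,I]	acylating_agent
sulfonyl_halide	S(=O)(=O)[F,Cl,Br,I]	acylating_agent
anhydride	C(=O)OC(=O)	acylating_agent
aldehyde	[CX3H1]=O	aldehyde
hydroxamic_acid	C(=O)N[OX2H]	chelator
oxine_chelator	Oc1cccc2cccnc12	chelator
michael_acceptor	[CH2]=[CH][CX3]=[OX1]	reactive_electrophile
epoxide	C1OC1	reactive_electrophile
aziridine	C1CN1	reactive_electrophile
alkyl_halide_primary	[CX4;CH2][Br,I]	reactive_electrophile
isocyanate	N=C=O	isocyanate
isothiocyanate	N=C=S	isocyanate
azide	N=[N+]=[N-]	azide
diazo	C=[N+]=[N-]	azide
thiol	[SX2H]	thiol
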