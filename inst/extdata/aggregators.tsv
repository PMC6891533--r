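ref_id	smiles
AGG_clotrimazole	Clc1ccccc1C(c1ccccc1)(c1ccccc1)n1ccnc1
AGG_miconazole	Clc1ccc(C(Cn2ccnc2)OCc2ccc(Cl)cc2Cl)cc1Cl
AGG_dodecylphenol	CCCCCCCCCCCCc1ccccc1O
AGG_resveratrol	Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1
AGG_curcumin	COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O
AGG_quercetin	Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O
AGG_benzbromarone	CCc1oc2ccccc2c1C(=O)c1cc(Br)c(O)c(Br)c1
AGG_nonylphenol	CCCCCCCCCc1ccc(O)cc1
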