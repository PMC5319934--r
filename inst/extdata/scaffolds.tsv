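scaffold_id	template
anilide	O=C(Nc1cc{1}cc{2}c1)c1cc{3}ccc1
sulfonanilide	O=S(=O)(Nc1cc{1}cc{2}c1)c1cc{3}ccc1
diaryl_urea	O=C(Nc1cc{1}cc{2}c1)Nc1cc{3}ccc1
diphenylmethane	c1cc{1}cc(c1)Cc1cc{2}cc{3}c1
diaryl_ether	c1cc{1}cc(c1)Oc1cc{2}cc{3}c1
diarylamine	c1cc{1}cc(c1)Nc1cc{2}cc{3}c1
biphenyl	c1cc{1}cc(c1)-c1cc{2}cc{3}c1
phenylpiperazine	O=C(N1CCN(CC1)c1cc{1}cc{2}c1)c1cc{3}ccc1
piperidine_amine	c1cc{1}ccc1N1CCC(CC1)Nc1cc{2}cc{3}c1
azobenzene	c1cc{1}ccc1N=Nc1cc{2}cc{3}c1
indole_amide	O=C(Nc1cc{1}ccc1)c1cc2cc{2}cc{3}c2[nH]1
benzimidazole	c1c{1}cc2c(c1)nc([nH]2)Cc1cc{2}cc{3}c1
pyridine_amide	O=C(Nc1cc{1}cc{2}c1)c1cc{3}ncc1
pyrimidine_diamine	c1cc{1}cc(c1)Nc1nc{2}nc(c1)Nc1cc{3}ccc1
coumarin	O=c1cc{1}c2cc{2}cc{3}c2o1
naphthalene_amide	O=C(Nc1cc{1}cc{2}c1)c1ccc2cc{3}ccc2c1
thiophene_amide	O=C(Nc1cc{1}cc{2}c1)c1cc{3}cs1
furan_amide	O=C(Nc1cc{1}cc{2}c1)c1cc{3}co1
phenylpyrazole	c1cc{1}cc(c1)-n1nc{2}cc1-c1cc{3}ccc1
aryl_morpholine	c1c{1}cc{2}cc1N1CCOCC1
benzothiazole	c1c{1}cc2c(c1)sc(n2)Nc1cc{2}cc{3}c1
quinoline_amide	O=C(Nc1cc{1}cc{2}c1)c1cnc2cc{3}ccc2c1
piperidine_sulfonyl	O=S(=O)(N1CCCCC1)c1cc{1}cc{2}c1
benzofuran_amide	O=C(Nc1cc{1}cc{2}c1)c1cc2cc{3}ccc2o1
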