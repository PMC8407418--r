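type	name	member
marker	TIM	TIM
marker	TIM	tpiA
marker	TIM	EC 5.3.1.1
marker	GAPDH	GAPDH
marker	GAPDH	gap
marker	GAPDH	gapA
marker	GAPDH	EC 1.2.1.12
marker	PGK	PGK
marker	PGK	pgk
marker	PGK	EC 2.7.2.3
marker	NADH_dehydrogenase	NADH_dehydrogenase
marker	NADH_dehydrogenase	ndh
marker	NADH_dehydrogenase	nuoB
marker	NADH_dehydrogenase	EC 1.6.5.3
marker	ctaB	ctaB
marker	ctaB	EC 2.5.1.141
marker	PPA	PPA
marker	PPA	ppa
marker	PPA	EC 3.6.1.1
marker	sdhA	sdhA
marker	sdhA	frdA
marker	sdhA	EC 1.3.5.1
marker	sdhA	EC 1.3.5.4
pathway	F_type_ATPase	atpA
pathway	F_type_ATPase	atpB
pathway	F_type_ATPase	atpC
pathway	F_type_ATPase	atpD
pathway	F_type_ATPase	atpE
pathway	F_type_ATPase	atpF
pathway	F_type_ATPase	atpG
pathway	F_type_ATPase	atpH
pathway	TCA	gltA
pathway	TCA	acnA
pathway	TCA	icd
pathway	TCA	sucA
pathway	TCA	sucC
pathway	TCA	sucD
pathway	TCA	sdhA
pathway	TCA	fumC
pathway	TCA	mdh
pathway	AA	ilvA
pathway	AA	leuA
pathway	AA	trpA
pathway	AA	hisB
pathway	AA	argB
pathway	AA	lysA
pathway	AA	serA
pathway	AA	thrC
pathway	Lip	accA
pathway	Lip	accB
pathway	Lip	accD
pathway	Lip	fabD
pathway	Lip	fabF
pathway	Lip	fabG
pathway	Lip	fabH
pathway	Lip	fabZ
pathway	Lip	plsX
pathway	Pur	purA
pathway	Pur	purB
pathway	Pur	purC
pathway	Pur	purD
pathway	Pur	purE
pathway	Pur	purF
pathway	Pur	purH
pathway	Pur	purL
pathway	Pur	purM
pathway	Pyr	pyrB
pathway	Pyr	pyrC
pathway	Pyr	pyrD
pathway	Pyr	pyrE
pathway	Pyr	pyrF
pathway	Pyr	pyrG
pathway	Pyr	pyrH
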