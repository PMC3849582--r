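optic_chiasm	curated fly small phenotype gene set	bi	rst	so	sim	ato	tutl	Scer\GAL4	elav
CNS_glial_cell	curated fly small phenotype gene set	E(z)	sws	gcm	Scer\GAL4	spdo	hkb	vnd
adult_myoblast	curated fly small phenotype gene set	slou	N	Rac1	insc	Scer\GAL4	Hsap\CDKN1A	tw
sex_comb_tooth	curated fly small phenotype gene set	Pc	Scr	ph-p	Scer\GAL4	KG01932	5-SZ-3716	Zzzz\Aobl-tra
abdominal_3_seg._border_muscle	curated fly small phenotype gene set	if	numb	mys	insc	Tig	Scer\GAL4
epidermal_cell	curated fly small phenotype gene set	ed	pim	tkv	ct	Scer\GAL4	exo84
glomerulus	curated fly small phenotype gene set	dnc	Wnt5	Cdc42	Scer\GAL4	drl	Drl-2
mesothoracic_cleft	curated fly small phenotype gene set	bsk	kay	pnr	Scer\GAL4	park	puc
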