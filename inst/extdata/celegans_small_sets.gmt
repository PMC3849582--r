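neuron_function_reduced	curated worm small phenotype gene set	F36F2.5(tax-2)	F55A8.2(egl-4)	K03A11.3(ceh-28)	K03A11.8	ZC416.8(unc-17)	ZC84.2(tax-4)	ZK1290.18	ZK1290.2(tph-1)
neuron_morphology_variant	curated worm small phenotype gene set	C10A4.8(mnm-2)	C35C5.4(mig-2)	C44B11.3(mec-12)	F28D1.10(gex-3)	K10G9.3(pad-2)	T01E8.4	Y51H4A.3	ZK154.3(mec-7)
pheromone_induced_dauer_form._enhan	curated worm small phenotype gene set	C38C3.5(unc-60)	F02E8.6(ncr-1)	F02E8.9	F55A8.2(egl-4)	T20B5.3(oga-1)	Y44A6D.4(sdf-9)	Y6B3B.11(hsd-1)
programmed_cell_death_variant	curated worm small phenotype gene set	C07H6.7(lin-39)	C09G4.1(hyl-1)	F31E3.1(ceh-20)	T07C4.8(ced-9)	T12F5.4(lin-59)	T28F12.2(unc-62)	Y6B3B.10(lag-1)
cell_division_slow	curated worm small phenotype gene set	C26D10.1(ran-3)	C29E4.3(ran-2)	F26B1.3(ima-2)	F28B3.8(imb-1)	K01G5.4(ran-1)	ZK328.5(npp-10)
ectopic_neurite_outgrowth	curated worm small phenotype gene set	B0285.5(hse-5)	C35C5.4(mig-2)	C39F7.2	F41C6.1(unc-6)	T19B4.7(unc-40)	T24B8.6(hlh-3)
dauer_cuticle_variant	curated worm small phenotype gene set	C47G2.1(cut-1)	C47G2.15	F22B5.3(cut-3)	M142.2(cut-6)	ZC328.1
endosome_biogenesis_variant	curated worm small phenotype gene set	F49E7.1(rme-6)	F58G6.1(amph-1)	W06B4.3(vps-18)	Y39A1A.5(rabx-5)	Y49E10.11(tat-1)
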