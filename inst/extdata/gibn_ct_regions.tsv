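set_name	region
CT1	banks superior temporal sulcus
CT1	caudal middle frontal
CT1	inferior parietal
CT1	paracentral
CT1	pars opercularis
CT1	postcentral
CT1	precentral
CT1	precuneus
CT1	rostral middle frontal
CT1	superior frontal
CT1	superior parietal
CT1	supramarginal
CT2	caudal anterior cingulate
CT2	frontal pole
CT2	insula
CT2	lateral orbitofrontal
CT2	medial orbitofrontal
CT2	pars orbitalis
CT2	rostral anterior cingulate
CT2	rostral middle frontal
CT3	banks superior temporal sulcus
CT3	superior temporal
CT3	temporal pole
CT4	cuneus
CT4	lateral occipital
CT4	parahippocampal
CT4	pericalcarine
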