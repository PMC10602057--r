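set_name	region
SA1	inferior temporal
SA1	isthmus cingulate
SA1	postcentral
SA1	precuneus
SA1	superior parietal
SA1	supramarginal
SA1	temporal pole
SA2	caudal anterior cingulate
SA2	caudal middle frontal
SA2	medial orbitofrontal
SA2	paracentral
SA2	rostral anterior cingulate
SA3	banks superior temporal sulcus
SA3	inferior parietal
SA3	middle temporal
SA4	pars opercularis
SA4	pars orbitalis
SA4	pars triangularis
SA5	cuneus
SA5	lateral occipital
SA5	lingual
SA5	pericalcarine
SA6	superior temporal
SA6	transverse temporal
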