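banks superior temporal sulcus
caudal anterior cingulate
caudal middle frontal
cuneus
entorhinal
frontal pole
fusiform
inferior parietal
inferior temporal
insula
isthmus cingulate
lateral occipital
lateral orbitofrontal
lingual
medial orbitofrontal
middle temporal
paracentral
parahippocampal
pars opercularis
pars orbitalis
pars triangularis
pericalcarine
postcentral
posterior cingulate
precentral
precuneus
rostral anterior cingulate
rostral middle frontal
superior frontal
superior parietal
superior temporal
supramarginal
temporal pole
transverse temporal
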