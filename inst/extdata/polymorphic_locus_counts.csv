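marker_system,group,n_samples,n_loci,n_polymorphic
MSAP,Control,5,102,23
MSAP,GR,24,102,41
MSAP,DNMTi,16,102,39
MSAP,DNMTi+GR,48,102,61
MSAP,Total,93,102,66
TMD,Control,5,60,15
TMD,GR,24,60,24
TMD,DNMTi,16,60,29
TMD,DNMTi+GR,48,60,34
TMD,Total,93,60,41
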