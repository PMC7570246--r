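group,n_I,n_II,n_III,n_IV
Control,97,53,16,61
G100,148,54,45,119
G150,162,52,46,126
G250,164,55,48,127
A80,166,51,66,115
Z80,167,49,64,112
A80+G100,254,44,115,127
A80+G150,266,43,121,132
Z80+G100,287,44,121,133
Z80+G150,299,41,130,121
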