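group,n_I,n_II,n_III,n_IV
Control,221,70,102,142
G100,336,100,126,246
G150,337,67,97,317
G250,338,84,84,288
A80,363,57,54,331
Z80,362,59,48,324
A80+G100,573,90,83,498
A80+G150,580,92,78,512
Z80+G100,550,96,82,485
Z80+G150,586,102,46,503
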