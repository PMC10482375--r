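sA2_chr	1200000	1245000
rB1_chr	2690000	2730000
eC1_chr	3050000	3110000
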