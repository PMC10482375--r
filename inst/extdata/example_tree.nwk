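((sA1:0.4,sA2:0.4):0.6,(rB1:0.7,eC1:0.7):0.3);
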