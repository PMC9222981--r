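code,parent,delta_formula
m62A,A,C2H4
hm5C,C,CH2O
mU,U,CH2
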