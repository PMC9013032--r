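code,level
J9601,MCC
N170,MCC
I5023,MCC
E8770,CC
E1122,CC
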