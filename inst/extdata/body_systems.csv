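code,body_system
I10,7
E8770,3
J9601,8
N170,10
D649,4
Z3800,15
I5023,7
E1122,3
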