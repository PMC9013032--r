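code,category
I10,HTN
E8770,LYTES
D649,ANEMDEF
I5023,CHF
E1122,DMCX
N170,RENLFAIL
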