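intraop,I,IIa,IIb,III
I,20,1,0,0
IIa,14,10,3,2
IIb,15,11,5,4
III,1,2,0,11
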