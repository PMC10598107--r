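intraop,I,IIa,IIb,III
I,21,0,0,0
IIa,1,23,3,2
IIb,6,7,17,5
III,0,1,0,13
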