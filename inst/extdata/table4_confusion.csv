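phase,1,2,3,4
A,22,0,0,1
B,45,0,0,8
C,0,7,2,0
D,27,1,0,37
E,0,0,1,0
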