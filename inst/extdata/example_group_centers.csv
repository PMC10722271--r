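group,x,y
A,1700,1600
B,2300,1600
C,1700,2400
D,2300,2400
E,10000,2000
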