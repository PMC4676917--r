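construct,dH,dCp,Tm_C
Wt,19.2,2.24,33.6
E89,29.5,1.73,37.2
E112,30.0,1.73,37.3
E103,31.3,1.69,38.9
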