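# Continuous unscripted monitoring, young volunteers (fall-free): minutes worn and false positives
volunteer,time_min,fp
F_6,79.1,0
M_3,74.8,1
M_5,84.2,0
F_7,67.6,2
M_2,79.4,0
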