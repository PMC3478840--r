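# Continuous unscripted monitoring, elderly volunteers (fall-free): minutes worn and false positives
volunteer,time_min,fp
EF_1,72.1,0
EF_2,71.1,0
EF_3,76.2,1
EF_4,76.3,0
EM_5,68.1,0
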