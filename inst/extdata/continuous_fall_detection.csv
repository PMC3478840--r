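# Continuous unscripted sessions with three embedded falls per subject: event-level counts
volunteer,tp,fn,fp
CM_1,2,1,0
CM_2,3,0,0
CM_3,3,0,0
CM_4,2,1,0
CM_5,3,0,0
CF_6,3,0,0
CF_7,2,1,0
CF_8,3,0,0
CF_9,3,0,0
CF_10,3,0,0
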