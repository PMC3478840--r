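# Scripted-trial testing: misclassified cases per ADL class among 500 falling / 550 non-falling test instances
adl_id,n_false,n_total
1,4,500
2,2,500
3,0,500
4,1,500
5,0,500
6,2,500
7,2,500
8,0,500
9,2,500
10,0,500
11,0,550
12,2,550
13,0,550
14,1,550
15,0,550
16,0,550
17,0,550
18,0,550
19,0,550
20,1,550
21,0,550
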