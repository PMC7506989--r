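expert,Awa,REM,S1,S2,S3,S4
Awa,73165,483,46,141,0,0
REM,876,4819,61,988,0,0
S1,578,1174,583,682,0,0
S2,375,863,76,15631,254,50
S3,71,0,0,1003,1055,159
S4,23,0,0,171,256,1060
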