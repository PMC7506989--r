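expert,Awa,REM,S1,S2,S3,S4
Awa,5247,96,85,155,3,15
REM,203,3697,86,566,1,2
S1,418,784,257,328,1,0
S2,262,731,62,11852,248,119
S3,20,0,0,1022,543,527
S4,174,0,0,231,271,2395
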