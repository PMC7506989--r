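expert,Awa,REM,N1,N2,N3
Awa,3306,53,68,111,21
REM,131,2452,93,330,13
N1,341,480,260,389,10
N2,229,499,50,7056,417
N3,77,1,0,761,3117
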