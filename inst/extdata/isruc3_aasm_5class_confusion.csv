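expert,Awa,REM,N1,N2,N3
Awa,1537,13,84,53,15
REM,36,1032,89,68,13
N1,91,135,648,242,7
N2,68,85,128,2312,257
N3,15,1,2,229,1729
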