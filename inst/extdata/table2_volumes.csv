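subject,group,microct_bridging_pct,volume_mm3
NS1,NS,0,5793
NS2,NS,5,6289
NS3,NS,24,6961
BMP1,BMP,100,7514
BMP2,BMP,90,7586
BMP3,BMP,81,7763
Dipy1,DIPY,2,5936
Dipy2,DIPY,4,6325
Dipy3,DIPY,22,7137
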