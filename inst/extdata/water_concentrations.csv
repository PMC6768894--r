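sn,gender,session,c_water_MBq_per_m3
1,F,1,0.720
1,F,2,0.880
2,F,1,0.830
2,F,2,0.860
3,F,1,0.960
4,F,1,0.870
4,F,2,0.840
5,M,1,0.890
6,M,1,0.870
6,M,2,0.700
6,M,3,0.815
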