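sn,session_type,rt_Bq,rt_per_rn_Bq_per_MBq_m3,rt_per_rn_bsa_Bq_per_MBq_m5
1,bath20,655,899,545
1,bath20,851,939,569
2,bath20,658,778,512
2,preheated,1718,1909,1256
3,bath20,612,626,394
4,bath20,689,771,459
4,bath30,1479,1732,1031
5,bath20,1176,1304,609
6,bath20,1055,1182,568
6,bath30,2728,3213,1545
6,preheated,1559,2267,1090
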