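sn,gender,age_y,height_cm,mass_kg,bsa_m2,body_fat_kg,frc_l,v_rt_l,v_t_l,rf_per_min,rmv_l_per_h
1,F,36,168,58,1.65,17.7,2.78,3.25,0.56,15.3,514
2,F,26,160,52,1.52,10.8,2.61,3.05,0.52,20.5,640
3,F,28,160,57,1.59,14.3,2.61,3.05,0.52,13.9,434
4,F,32,163,62,1.68,19.0,2.62,3.06,0.52,15.0,468
5,M,40,184,90,2.14,21.0,3.58,4.19,0.72,14.0,605
6,M,28,187,83,2.08,19.7,3.54,4.14,0.70,11.1,466
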