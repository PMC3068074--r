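t_category,psa_min,psa_max,gleason_min,gleason_max,organ_confined_pct,extraprostatic_pct,seminal_vesicle_pct,lymph_node_pct
T1c,0,4,2,6,90,7,2,1
T1c,0,4,7,7,80,12,5,3
T1c,0,4,8,10,69,19,7,5
T1c,4,10,2,6,82,11,4,3
T1c,4,10,7,7,71,17,7,5
T1c,4,10,8,10,61,22,10,7
T1c,10,20,2,6,74,16,6,4
T1c,10,20,7,7,63,22,9,6
T1c,10,20,8,10,53,27,12,8
T1c,20,,2,6,66,20,8,6
T1c,20,,7,7,55,26,11,8
T1c,20,,8,10,45,31,14,10
T2a,0,4,2,6,82,11,4,3
T2a,0,4,7,7,71,17,7,5
T2a,0,4,8,10,61,22,10,7
T2a,4,10,2,6,74,16,6,4
T2a,4,10,7,7,63,22,9,6
T2a,4,10,8,10,53,27,12,8
T2a,10,20,2,6,66,20,8,6
T2a,10,20,7,7,55,26,11,8
T2a,10,20,8,10,45,31,14,10
T2a,20,,2,6,57,25,10,8
T2a,20,,7,7,47,30,13,10
T2a,20,,8,10,36,36,16,12
T2b,0,4,2,6,74,16,6,4
T2b,0,4,7,7,63,22,9,6
T2b,0,4,8,10,53,27,12,8
T2b,4,10,2,6,66,20,8,6
T2b,4,10,7,7,55,26,11,8
T2b,4,10,8,10,45,31,14,10
T2b,10,20,2,6,57,25,10,8
T2b,10,20,7,7,47,30,13,10
T2b,10,20,8,10,36,36,16,12
T2b,20,,2,6,49,30,12,9
T2b,20,,7,7,39,35,15,11
T2b,20,,8,10,28,41,18,13
T2c,0,4,2,6,66,20,8,6
T2c,0,4,7,7,55,26,11,8
T2c,0,4,8,10,45,31,14,10
T2c,4,10,2,6,57,25,10,8
T2c,4,10,7,7,47,30,13,10
T2c,4,10,8,10,36,36,16,12
T2c,10,20,2,6,49,30,12,9
T2c,10,20,7,7,39,35,15,11
T2c,10,20,8,10,28,41,18,13
T2c,20,,2,6,41,33,15,11
T2c,20,,7,7,30,40,17,13
T2c,20,,8,10,20,45,20,15
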