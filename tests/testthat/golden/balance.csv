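# ccwmsm 0.1.0 seed=7
covariate,smd_unweighted,smd_weighted
age,0.244486406312156,0.0861676622647349
sex,0.0089755614024596,0.0433714819108715
charlson_ge2,0.0412990589185417,0.0559117806352349
crp,0.282940009074973,0.0900167514151104
ldh,0.0345747289263064,0.0871267729885638
log_ddimer,0.163968483689959,0.0169230501592576
lymphocytes,0.23509476428555,0.212417625974043
wave2,0.10031769411259,0.0185419899452494
wave3,0.0910926377301245,0.0375548830898574
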