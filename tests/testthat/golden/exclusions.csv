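# ccwmsm 0.1.0 seed=7
rule,n_excluded
hospital_acquired,5
readmission,3
pre_admission_treatment,1
outcome_day0,2
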