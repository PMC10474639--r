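patient_id,arm,censor_day,censor_indicator,followup_end,end_reason,terminal_state,icu_day,event_day,event_state,sex
1,control,2,1,2,artificial_censor,1,,,,1
2,control,2,1,2,artificial_censor,1,,,,0
3,control,4,1,4,artificial_censor,1,,,,1
4,control,,0,3,event,3,,3,3,0
5,control,,0,1,event,4,,1,4,1
6,control,1,1,1,artificial_censor,1,,,,0
7,control,,0,45,administrative,2,6,,,1
8,control,,0,8,event,3,2,8,3,0
9,control,5,1,5,artificial_censor,1,,,,1
10,control,,0,45,administrative,1,,,,0
11,control,,0,4,event,5,,4,5,1
12,control,3,1,3,artificial_censor,1,,,,0
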