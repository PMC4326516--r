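patient,diagnosis,global_t2_ms,global_t2_sd_ms
1,acute diffuse myocarditis,68.0,2.4
2,acute myocardial infarction,62.5,13.1
3,takotsubo cardiomyopathy,63.5,6.0
4,acute myocarditis,57.7,8.7
5,acute myocardial infarction,54.8,4.1
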