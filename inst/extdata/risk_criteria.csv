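group,logic,t_stages,psa_min,psa_max,gleason_min,gleason_max,failure_lo,failure_hi,surv5,surv10
high,any,T2c,20,,8,10,50,,30,29
intermediate,any,T2b,10,20,7,7,25,50,60,46
low,all,T1c;T2a,,10,2,6,,25,85,83
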