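cohort,acute_phase,beta_sjc,beta_ap,n_obs,n_missing_ap
IACON,CRP,30.61,15.45,889,53
IDEA,CRP,31.40,40.31,163,9
PEAC,CRP,4.69,4.06,183,5
IACON,ESR,32.30,11.74,889,159
IDEA,ESR,47.70,12.68,163,10
PEAC,ESR,5.59,1.43,183,3
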