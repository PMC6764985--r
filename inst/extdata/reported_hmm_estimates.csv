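parameter,state,sex,estimate,lo95,hi95
mu,transit,female,5.15,4.78,5.51
mu,transit,male,3.16,2.94,3.38
mu,transit,unknown,4.00,3.69,4.30
mu,resident,female,2.15,1.92,2.38
mu,resident,male,0.89,0.85,0.93
mu,resident,unknown,0.85,0.79,0.90
kappa,transit,female,0.62,0.56,0.68
kappa,transit,male,0.38,0.31,0.44
kappa,transit,unknown,0.60,0.53,0.66
ptr,all,all,0.035,0.025,0.049
prt,all,all,0.017,0.011,0.024
resident_time_pct,all,all,66,65,68
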