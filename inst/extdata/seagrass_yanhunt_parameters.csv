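species,season,location,p_max,p_max_se,t_opt,t_opt_se,t_max,t_max_se,p0,p0_se,q10,q10_se,adj_r2
C. serrulata,summer,Green Island,3.9,0.2,34.9,0.5,43.7,0.3,1.3,0.2,2.4,0.3,0.76
C. serrulata,summer,Moreton Bay,3.9,0.1,35.4,0.3,44.2,0.3,1.3,0.1,2.2,0.2,0.84
C. serrulata,winter,Moreton Bay,2.9,0.1,35.8,0.3,44.7,0.3,0.8,0.1,2.7,0.2,0.84
H. uninervis,summer,Green Island,3.9,0.3,34.0,0.9,44.6,0.9,1.5,0.3,2.7,0.7,0.44
H. uninervis,summer,Moreton Bay,5.2,0.1,35.8,0.2,44.4,0.2,1.6,0.1,2.4,0.2,0.90
H. uninervis,winter,Moreton Bay,5.5,0.2,34.9,0.3,44.6,0.3,2.1,0.2,2.1,0.2,0.85
Z. muelleri,summer,Moreton Bay,4.3,0.3,30.9,1.0,43.6,0.7,2.5,0.4,2.2,0.4,0.55
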