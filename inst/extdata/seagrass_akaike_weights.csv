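species,season,location,Briere1,Briere2,Deutsch,Johnson,Lactin,ONeill,Ratkowsky,Room,Spain,Thebault,VanDerHeide,YanHunt
C. serrulata,summer,Green Island,0.0977,0.0859,0.1030,0.0566,0.0933,0.0880,0.1221,0.1320,0.0075,0.0001,0.0166,0.1974
C. serrulata,summer,Moreton Bay,0.0720,0.0635,0.0819,0.1026,0.1190,0.1551,0.1438,0.0859,0.0827,0.0000,0.0000,0.0937
C. serrulata,winter,Moreton Bay,0.0005,0.0005,0.0030,0.8553,0.0019,0.0541,0.0070,0.0037,0.0011,0.0630,0.0000,0.0100
H. uninervis,summer,Green Island,0.0510,0.1104,0.1310,0.0575,0.0247,0.0531,0.1114,0.0921,0.0054,0.0409,0.2170,0.1056
H. uninervis,summer,Moreton Bay,0.0136,0.0135,0.0808,0.1709,0.0535,0.2602,0.1170,0.0914,0.0188,0.0000,0.0000,0.1804
H. uninervis,winter,Moreton Bay,0.3373,0.1639,0.1126,0.0018,0.0861,0.0193,0.0589,0.1050,0.0067,0.0000,0.0006,0.1079
Z. muelleri,summer,Moreton Bay,0.0000,0.1096,0.1087,0.2172,0.0000,0.0812,0.1103,0.2264,0.0000,0.1405,0.0046,0.0016
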