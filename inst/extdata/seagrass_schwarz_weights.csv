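species,season,location,Briere1,Briere2,Deutsch,Johnson,Lactin,ONeill,Ratkowsky,Room,Spain,Thebault,VanDerHeide,YanHunt
C. serrulata,summer,Green Island,0.1451,0.0670,0.0804,0.0442,0.0728,0.0686,0.0952,0.1030,0.0058,0.0000,0.0246,0.2932
C. serrulata,summer,Moreton Bay,0.1193,0.0552,0.0712,0.0892,0.1035,0.1349,0.1250,0.0747,0.0719,0.0000,0.0000,0.1551
C. serrulata,winter,Moreton Bay,0.0009,0.0005,0.0029,0.8472,0.0018,0.0536,0.0069,0.0037,0.0011,0.0624,0.0000,0.0189
H. uninervis,summer,Green Island,0.0726,0.0825,0.0979,0.0430,0.0185,0.0397,0.0832,0.0688,0.0040,0.0306,0.3089,0.1502
H. uninervis,summer,Moreton Bay,0.0220,0.0115,0.0688,0.1454,0.0455,0.2214,0.0995,0.0777,0.0160,0.0000,0.0000,0.2922
H. uninervis,winter,Moreton Bay,0.4578,0.1168,0.0802,0.0013,0.0613,0.0138,0.0420,0.0748,0.0048,0.0000,0.0008,0.1465
Z. muelleri,summer,Moreton Bay,0.0000,0.1090,0.1082,0.2162,0.0000,0.0809,0.1098,0.2253,0.0000,0.1398,0.0080,0.0028
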