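variant,region,tm_c,tm_se_c,delta_tm_printed,delta_tm_se_printed,kd_nm,kd_se_nm,dg_printed,dg_se_printed,ddg_printed,ddg_se_printed
wt,,54.0,0.1,,,18,0,-10.56,0.01,,
Phe337Ala,alpha-helix,53.1,0.1,-0.9,0.1,202,8,-9.12,0.02,1.43,0.02
Tyr369Ala,alpha-helix,49.9,0.2,-4.2,0.3,,,,,,
Phe373Ala,alpha-helix,53.0,0.3,-1.0,0.3,12,0,-10.79,0.00,-0.24,0.01
Lys376Ala,alpha-helix,53.4,0.1,-0.7,0.1,203,9,-9.13,0.03,1.43,0.03
Leu377Ala,alpha-helix,49.8,0.1,-4.3,0.2,,,,,,
Leu380Ala,alpha-helix,52.8,0.1,-1.3,0.2,162,7,-9.26,0.03,1.30,0.03
Val389Ala,alpha-helix,53.0,0.0,-1.0,0.1,304,5,-8.88,0.01,1.67,0.01
Glu263Ala,omega-loop,53.0,0.2,-1.1,0.2,220,9,-9.07,0.02,1.48,0.03
Val265Ala,omega-loop,52.0,0.0,-2.0,0.1,106,3,-9.51,0.02,1.05,0.02
Asp272Ala,omega-loop,54.1,0.1,0.1,0.1,6995,317,-7.03,0.03,3.53,0.03
Lys273Ala,omega-loop,48.1,0.2,-5.9,0.3,,,,,,
Leu295Ala,omega-loop,47.4,0.1,-6.6,0.1,,,,,,
Lys297Ala,omega-loop,48.4,0.2,-5.7,0.3,,,,,,
Val414Ala,omega-loop,50.9,0.1,-3.2,0.1,14,1,-10.73,0.02,-0.17,0.02
Tyr429Phe,omega-loop,52.3,0.1,-1.7,0.1,71,6,-9.75,0.05,0.81,0.05
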