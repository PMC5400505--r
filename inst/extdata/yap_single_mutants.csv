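variant,region,kd_nm,kd_se_nm,dg_printed,dg_se_printed,ddg_printed,ddg_se_printed
wt,,18,0,-10.56,0.01,,
Leu65Ala,alpha-helix,794,4,-8.31,0.01,2.24,0.01
Leu68Ala,alpha-helix,464,4,-8.63,0.01,1.92,0.01
Phe69Ala,alpha-helix,6447,400,-7.08,0.04,3.48,0.04
Met86Ala,omega-loop,2080,69,-7.74,0.02,2.81,0.02
Arg89Ala,omega-loop,27423,381,-6.22,0.01,4.34,0.01
Leu91Ala,omega-loop,30550,2250,-6.15,0.04,4.40,0.05
Ser94Ala,omega-loop,5623,341,-7.16,0.04,3.40,0.04
Phe95Ala,omega-loop,26045,755,-6.25,0.02,4.31,0.02
Phe96Ala,omega-loop,4755,245,-7.25,0.03,3.30,0.03
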