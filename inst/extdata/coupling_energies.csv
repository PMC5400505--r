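yap_variant,tead_variant,ddg_int,ddg_int_se,measurable
Leu65Ala,Phe337Ala,-0.34,0.04,1
Leu68Ala,Phe337Ala,-0.65,0.04,1
Phe69Ala,Phe337Ala,-0.96,0.04,1
Met86Ala,Phe337Ala,0.17,0.04,1
Arg89Ala,Phe337Ala,-0.44,0.03,1
Leu91Ala,Phe337Ala,,,0
Ser94Ala,Phe337Ala,-0.09,0.05,1
Phe95Ala,Phe337Ala,,,0
Phe96Ala,Phe337Ala,0.02,0.06,1
Leu65Ala,Lys376Ala,-0.65,0.04,1
Leu68Ala,Lys376Ala,-0.41,0.05,1
Phe69Ala,Lys376Ala,-1.28,0.06,1
Met86Ala,Lys376Ala,0.13,0.04,1
Arg89Ala,Lys376Ala,-0.62,0.03,1
Leu91Ala,Lys376Ala,-0.41,0.06,1
Ser94Ala,Lys376Ala,-0.22,0.06,1
Phe95Ala,Lys376Ala,-0.30,0.04,1
Phe96Ala,Lys376Ala,-0.14,0.05,1
Leu65Ala,Leu380Ala,-0.36,0.05,1
Leu68Ala,Leu380Ala,-0.29,0.04,1
Phe69Ala,Leu380Ala,-1.01,0.06,1
Met86Ala,Leu380Ala,0.07,0.03,1
Arg89Ala,Leu380Ala,-0.29,0.03,1
Leu91Ala,Leu380Ala,-0.26,0.05,1
Ser94Ala,Leu380Ala,-0.08,0.05,1
Phe95Ala,Leu380Ala,-0.18,0.03,1
Phe96Ala,Leu380Ala,-0.02,0.06,1
Leu65Ala,Val389Ala,-0.52,0.06,1
Leu68Ala,Val389Ala,-0.29,0.05,1
Phe69Ala,Val389Ala,-1.11,0.05,1
Met86Ala,Val389Ala,0.16,0.03,1
Arg89Ala,Val389Ala,,,0
Leu91Ala,Val389Ala,,,0
Ser94Ala,Val389Ala,0.03,0.05,1
Phe95Ala,Val389Ala,,,0
Phe96Ala,Val389Ala,-0.06,0.04,1
Leu65Ala,Glu263Ala,-0.05,0.05,1
Leu68Ala,Glu263Ala,-0.09,0.03,1
Phe69Ala,Glu263Ala,-0.10,0.06,1
Met86Ala,Glu263Ala,0.07,0.05,1
Arg89Ala,Glu263Ala,-0.59,0.06,1
Leu91Ala,Glu263Ala,-0.62,0.05,1
Ser94Ala,Glu263Ala,-0.96,0.05,1
Phe95Ala,Glu263Ala,-0.51,0.05,1
Phe96Ala,Glu263Ala,-0.04,0.07,1
Leu65Ala,Val265Ala,0.26,0.03,1
Leu68Ala,Val265Ala,0.15,0.03,1
Phe69Ala,Val265Ala,0.13,0.05,1
Met86Ala,Val265Ala,0.09,0.03,1
Arg89Ala,Val265Ala,-0.58,0.02,1
Leu91Ala,Val265Ala,-0.28,0.06,1
Ser94Ala,Val265Ala,-0.06,0.06,1
Phe95Ala,Val265Ala,-0.61,0.04,1
Phe96Ala,Val265Ala,-0.22,0.06,1
Leu65Ala,Asp272Ala,,,0
Leu68Ala,Asp272Ala,-0.02,0.04,1
Phe69Ala,Asp272Ala,,,0
Met86Ala,Asp272Ala,-1.85,0.04,1
Arg89Ala,Asp272Ala,-3.49,0.05,1
Leu91Ala,Asp272Ala,-2.74,0.06,1
Ser94Ala,Asp272Ala,-1.65,0.05,1
Phe95Ala,Asp272Ala,-2.50,0.07,1
Phe96Ala,Asp272Ala,-1.67,0.06,1
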