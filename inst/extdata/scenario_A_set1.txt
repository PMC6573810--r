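SNP	EAF	OR
s1_m1_o5	0.073	1.15
s1_m1_o4	0.073	1.125
s1_m1_o3	0.073	1.1
s1_m1_o2	0.073	1.075
s1_m1_o1	0.073	1.05
s1_m2_o5	0.18	1.15
s1_m2_o4	0.18	1.125
s1_m2_o3	0.18	1.1
s1_m2_o2	0.18	1.075
s1_m2_o1	0.18	1.05
s1_m3_o5	0.286	1.15
s1_m3_o4	0.286	1.125
s1_m3_o3	0.286	1.1
s1_m3_o2	0.286	1.075
s1_m3_o1	0.286	1.05
s1_m4_o5	0.393	1.15
s1_m4_o4	0.393	1.125
s1_m4_o3	0.393	1.1
s1_m4_o2	0.393	1.075
s1_m4_o1	0.393	1.05
s1_m5_o5	0.5	1.15
s1_m5_o4	0.5	1.125
s1_m5_o3	0.5	1.1
s1_m5_o2	0.5	1.075
s1_m5_o1	0.5	1.05
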