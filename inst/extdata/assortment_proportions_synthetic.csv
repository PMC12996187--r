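dbh_midpoint_cm,p_large,p_middle,p_small,p_short,p_fuel,p_bark
6,0.00,0.00,0.15,0.10,0.55,0.20
8,0.00,0.00,0.30,0.12,0.39,0.19
10,0.00,0.00,0.45,0.12,0.25,0.18
12,0.00,0.00,0.58,0.10,0.15,0.17
14,0.00,0.02,0.65,0.08,0.09,0.16
16,0.00,0.05,0.70,0.06,0.04,0.15
18,0.00,0.10,0.72,0.03,0.01,0.14
20,0.00,0.20,0.64,0.02,0.01,0.13
22,0.00,0.30,0.54,0.02,0.01,0.13
24,0.00,0.40,0.45,0.01,0.01,0.13
26,0.00,0.50,0.35,0.01,0.01,0.13
28,0.00,0.58,0.27,0.01,0.01,0.13
30,0.02,0.58,0.25,0.01,0.01,0.13
32,0.05,0.61,0.20,0.01,0.01,0.12
34,0.09,0.63,0.15,0.01,0.01,0.11
36,0.14,0.64,0.10,0.01,0.01,0.10
38,0.20,0.65,0.04,0.00,0.01,0.10
40,0.24,0.66,0.00,0.00,0.01,0.09
42,0.32,0.58,0.00,0.00,0.01,0.09
44,0.40,0.50,0.00,0.00,0.01,0.09
46,0.47,0.43,0.00,0.00,0.01,0.09
48,0.53,0.37,0.00,0.00,0.01,0.09
50,0.58,0.32,0.00,0.00,0.01,0.09
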