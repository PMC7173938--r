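n,L_a2,U_a2,L_a3,U_a3,L_a4,U_a4,L_a5,U_a5,L_a6,U_a6,L_a7,U_a7,L_a8,U_a8,L_a9,U_a9,L_a10,U_a10
2,0.000,1.000,0.000,1.000,0.000,1.000,0.000,1.000,0.000,1.000,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500
4,0.000,1.000,0.000,0.750,0.000,0.750,0.000,0.750,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500
6,0.167,0.833,0.000,0.833,0.000,0.667,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.333,0.000,0.333
8,0.125,0.875,0.000,0.630,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.375,0.000,0.375,0.000,0.375,0.000,0.375
10,0.200,0.800,0.100,0.600,0.000,0.500,0.000,0.500,0.000,0.400,0.000,0.400,0.000,0.300,0.000,0.300,0.000,0.300
15,0.267,0.733,0.133,0.533,0.067,0.467,0.000,0.400,0.000,0.333,0.000,0.333,0.000,0.267,0.000,0.267,0.000,0.267
20,0.300,0.700,0.150,0.500,0.100,0.450,0.050,0.350,0.000,0.350,0.000,0.300,0.000,0.250,0.000,0.250,0.000,0.250
25,0.320,0.680,0.160,0.480,0.120,0.400,0.080,0.360,0.040,0.320,0.040,0.280,0.000,0.240,0.000,0.200,0.000,0.200
30,0.333,0.667,0.200,0.467,0.100,0.400,0.067,0.333,0.067,0.300,0.033,0.267,0.033,0.233,0.000,0.200,0.000,0.200
40,0.375,0.625,0.200,0.450,0.125,0.375,0.100,0.300,0.080,0.275,0.050,0.250,0.050,0.225,0.025,0.200,0.025,0.200
50,0.380,0.630,0.220,0.440,0.140,0.360,0.100,0.300,0.080,0.260,0.060,0.220,0.040,0.200,0.040,0.200,0.002,0.180
100,0.430,0.570,0.260,0.400,0.190,0.310,0.140,0.260,0.110,0.220,0.090,0.200,0.070,0.180,0.060,0.160,0.050,0.150
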