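n,L_a2,U_a2,L_a3,U_a3,L_a4,U_a4,L_a5,U_a5,L_a6,U_a6,L_a7,U_a7,L_a8,U_a8,L_a9,U_a9,L_a10,U_a10
2,0.000,1.000,0.000,1.000,0.000,1.000,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500
4,0.000,1.000,0.000,0.750,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.250
6,0.167,0.833,0.000,0.667,0.000,0.500,0.000,0.500,0.000,0.500,0.000,0.333,0.000,0.333,0.000,0.333,0.000,0.333
8,0.250,0.750,0.125,0.625,0.000,0.500,0.000,0.375,0.000,0.375,0.000,0.375,0.000,0.375,0.000,0.250,0.000,0.250
10,0.300,0.700,0.100,0.600,0.000,0.500,0.000,0.400,0.000,0.400,0.000,0.300,0.000,0.300,0.000,0.300,0.000,0.300
15,0.333,0.667,0.133,0.533,0.067,0.400,0.067,0.333,0.000,0.333,0.000,0.267,0.000,0.267,0.000,0.267,0.000,0.200
20,0.350,0.650,0.200,0.500,0.100,0.400,0.050,0.350,0.050,0.300,0.050,0.250,0.000,0.250,0.000,0.200,0.000,0.200
25,0.360,0.640,0.200,0.440,0.120,0.360,0.080,0.320,0.040,0.280,0.040,0.240,0.040,0.240,0.000,0.200,0.000,0.200
30,0.367,0.633,0.233,0.433,0.133,0.367,0.100,0.300,0.067,0.267,0.067,0.233,0.033,0.200,0.033,0.200,0.033,0.167
40,0.400,0.600,0.250,0.425,0.150,0.325,0.125,0.275,0.080,0.250,0.075,0.225,0.050,0.200,0.050,0.180,0.025,0.175
50,0.420,0.580,0.260,0.400,0.180,0.320,0.120,0.260,0.100,0.210,0.080,0.200,0.060,0.180,0.040,0.180,0.040,0.160
100,0.460,0.540,0.290,0.380,0.210,0.290,0.160,0.240,0.120,0.210,0.100,0.180,0.080,0.160,0.070,0.150,0.060,0.140
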