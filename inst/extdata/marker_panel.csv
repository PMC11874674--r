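locus,motif,n,n_alleles,size_min,size_max,ho,he,p_hwe,multiplex
Smu012,AC,81,12,202,234,0.73,0.8,0.278,1
Smu071,AC,81,15,132,164,0.82,0.84,0.721,1
Smu085,AATG,81,5,319,335,0.6,0.68,0.052,1
Smu228,AC,81,20,95,139,0.96,0.93,0.766,1
Smu375,AC,81,8,306,330,0.73,0.75,0.375,1
Smu456,AG,81,21,186,224,0.9,0.91,0.426,1
Smu006,AG,81,8,228,252,0.72,0.76,0.365,2
Smu136,AC,81,19,83,129,0.85,0.83,0.573,2
Smu198,AC,81,8,208,228,0.63,0.64,0.953,2
Smu280,AGG,81,5,133,151,0.32,0.33,0.834,2
Smu408,AG,81,18,296,334,0.93,0.91,0.470,2
Smu185,AC,81,7,216,228,0.55,0.51,0.621,3
Smu308,AC,81,4,199,205,0.62,0.6,0.559,3
Smu318,AC,81,16,204,236,0.89,0.86,0.181,3
Smu328,ATC,81,4,262,278,0.48,0.49,0.816,3
Smu357,AG,81,22,238,274,0.88,0.89,0.062,3
Smu481,AC,81,7,118,132,0.75,0.77,0.589,3
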