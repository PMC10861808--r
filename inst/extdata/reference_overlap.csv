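subject,oc_uncseg_pM1p,oc_uncseg_mM1p,oc_uncseg_mM1m,oc_tractseg_pM1p,oc_tractseg_mM1p,oc_tractseg_mM1m,dice_uncseg_tractseg
1,1.000,0.684,0.395,1.000,0.387,0.024,0.820
2,0.941,0.000,0.000,0.980,0.000,0.000,0.853
3,0.864,0.000,0.000,0.857,0.000,0.000,0.869
4,0.868,0.310,0.011,0.919,0.468,0.107,0.814
5,0.785,0.000,0.000,0.780,0.000,0.000,0.862
6,0.774,0.000,0.000,0.816,0.000,0.000,0.821
7,0.808,0.000,0.000,0.922,0.000,0.000,0.805
8,0.504,0.000,0.000,0.540,0.000,0.000,0.846
9,0.993,0.343,0.291,1.000,0.622,0.318,0.847
10,0.851,0.000,0.333,0.823,0.000,0.000,0.765
11,0.828,0.000,0.053,0.761,0.000,0.000,0.862
12,0.660,0.055,0.000,0.741,0.000,0.000,0.809
13,0.677,0.075,0.077,0.787,0.000,0.000,0.838
14,1.000,0.375,0.000,1.000,0.125,0.000,0.855
15,0.724,0.000,0.000,0.897,0.000,0.000,0.687
16,0.944,0.006,0.069,0.944,0.026,0.106,0.864
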