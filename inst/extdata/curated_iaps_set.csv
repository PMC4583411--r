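image_id,valence_class
2020,neutral
2102,neutral
2104,neutral
2130,neutral
2190,neutral
2200,neutral
2271,neutral
2272,neutral
2280,neutral
2210,neutral
2214,neutral
2215,neutral
2220,neutral
2221,neutral
2230,neutral
2305,neutral
2357,neutral
2372,neutral
2383,neutral
2385,neutral
2393,neutral
2396,neutral
2397,neutral
2435,neutral
2441,neutral
2485,neutral
2487,neutral
2491,neutral
2493,neutral
2495,neutral
2499,neutral
2512,neutral
2513,neutral
2516,neutral
2520,neutral
2595,neutral
2635,neutral
2690,neutral
2704,neutral
2749,neutral
2770,neutral
2780,neutral
2795,neutral
2830,neutral
2840,neutral
2870,neutral
7506,neutral
1340,pleasant
1999,pleasant
2000,pleasant
2010,pleasant
2037,pleasant
2091,pleasant
2092,pleasant
2154,pleasant
2222,pleasant
2304,pleasant
2339,pleasant
2340,pleasant
2341,pleasant
2358,pleasant
2362,pleasant
2391,pleasant
2501,pleasant
2530,pleasant
2620,pleasant
2650,pleasant
4617,pleasant
5410,pleasant
7325,pleasant
8497,pleasant
2095,unpleasant
2110,unpleasant
2120,unpleasant
2141,unpleasant
2205,unpleasant
2276,unpleasant
2278,unpleasant
2490,unpleasant
2590,unpleasant
2691,unpleasant
2710,unpleasant
2750,unpleasant
3500,unpleasant
3530,unpleasant
4621,unpleasant
6243,unpleasant
6313,unpleasant
6315,unpleasant
6360,unpleasant
6370,unpleasant
6530,unpleasant
6550,unpleasant
6560,unpleasant
6561,unpleasant
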