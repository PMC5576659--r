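chain_id	ss_string	rsa_csv
syn0001	EHHCCHHCHCCCCEHEEHCCHCHEECCEHHHECCEHECEHECHHCCECHCECECCHHCCHHCCHECEEECCHEECCCCHEHCCHECCCHCHHHHHCHECH	0.5129,0.4466,0.6611,0.4448,0.1373,0.4724,0.4434,0.3266,0.2458,0.5337,0.5782,0.0173,0.1138,0.7484,0.5470,0.5791,0.2424,0.4233,0.7229,0.6165,0.3585,0.5532,0.4798,0.0617,0.3618,0.4603,0.3785,0.6569,0.6896,0.8303,0.4842,0.6970,0.5391,0.4598,0.7167,0.5566,0.1129,0.5071,0.4191,0.3610,0.2876,0.5399,0.5671,0.7026,0.7109,0.4035,0.4525,0.6002,0.5151,0.8337,0.1614,0.5240,0.5082,0.6232,0.2643,0.2774,0.3658,0.5389,0.1235,0.4275,0.3733,0.6394,0.4442,0.5031,0.0229,0.1210,0.2402,0.3676,0.8407,0.1510,0.3760,0.2245,0.5115,0.4286,0.5627,0.5317,0.1577,0.2489,0.6384,0.6259,0.4873,0.7362,0.5647,0.5351,0.6591,0.0246,0.1690,0.2135,0.6491,0.2203,0.8132,0.2764,0.6187,0.2098,0.4438,0.2414,0.0742,0.6058,0.5478,0.0702
syn0002	CCHECHEHCECHHCHHECHCCECCCHHCCCHECHHEHCHCHCEHECECCCHHEHHECEHHCECEEHHHECHCCHCCCECHHCHECECEHCHCECCCCCEC	0.6543,0.3663,0.6379,0.5072,0.3164,0.0498,0.1175,0.8105,0.4407,0.6723,0.5332,0.0618,0.4039,0.1096,0.1118,0.2753,0.7147,0.3082,0.7564,0.0355,0.6240,0.1142,0.1238,0.6071,0.4227,0.7736,0.6616,0.5680,0.4497,0.5239,0.2014,0.7022,0.5609,0.1038,0.5399,0.0699,0.5625,0.5222,0.4004,0.2871,0.4462,0.4373,0.6366,0.0425,0.2344,0.5856,0.6215,0.5553,0.6177,0.3763,0.0538,0.4375,0.7145,0.3313,0.2795,0.4412,0.6470,0.5362,0.7482,0.3961,0.1559,0.4281,0.3732,0.1507,0.1080,0.0602,0.8289,0.1657,0.3874,0.4128,0.1058,0.5365,0.2973,0.8094,0.3734,0.8154,0.3716,0.5330,0.0325,0.1056,0.5527,0.2046,0.4982,0.0876,0.4975,0.7117,0.3317,0.5106,0.6516,0.4554,0.6840,0.5732,0.8179,0.0307,0.0465,0.2146,0.5149,0.4968,0.6394,0.6373
syn0003	EEHCHCHCCHCCEEECHHHCHHHHECCCEHHCECCHCCCECECHEHHEECCCECCCCCHHCCCCCHHCCEEECCHCHCCHCCCCEEEECHEHHCCCCEHH	0.3361,0.0039,0.1546,0.4689,0.2115,0.3978,0.0439,0.6701,0.4009,0.0305,0.8050,0.7311,0.2971,0.4305,0.5480,0.6615,0.3194,0.5276,0.5816,0.6603,0.2656,0.7808,0.1753,0.3031,0.4889,0.4091,0.1696,0.7172,0.4050,0.1387,0.0660,0.7457,0.5751,0.4805,0.7522,0.0132,0.7568,0.2118,0.6205,0.3104,0.3097,0.6217,0.1299,0.6716,0.0081,0.1343,0.3988,0.5803,0.2982,0.5040,0.3647,0.1480,0.1216,0.0827,0.7604,0.3544,0.2213,0.3292,0.1479,0.4421,0.5180,0.0733,0.3294,0.6810,0.4775,0.6136,0.6808,0.2703,0.1136,0.5076,0.5063,0.6934,0.2423,0.2505,0.6384,0.1187,0.3230,0.6029,0.5646,0.1831,0.1799,0.3215,0.3055,0.2958,0.1469,0.4520,0.4740,0.3321,0.4485,0.5870,0.7598,0.2680,0.2044,0.3623,0.6428,0.5110,0.1773,0.7000,0.5030,0.4682
syn0004	EHHECEHHCCHHHEHHECCCCCHHEECECHCCCECHECEECCHHECHEHCHEHCHHECHCCECCCEHHCCEECECHEHCEECCHHEECCCCECCCCHHHC	0.6450,0.0540,0.4783,0.0079,0.1086,0.7079,0.2317,0.1082,0.7066,0.4481,0.1489,0.2347,0.2001,0.3740,0.3832,0.5824,0.7086,0.2836,0.5766,0.2374,0.1773,0.5576,0.1902,0.3681,0.7577,0.2944,0.5048,0.3683,0.0371,0.4580,0.0790,0.1321,0.7955,0.7538,0.0106,0.2165,0.2961,0.3343,0.5016,0.2199,0.4034,0.5794,0.3040,0.0024,0.1278,0.5959,0.0734,0.3775,0.3959,0.2178,0.2500,0.5392,0.6890,0.1246,0.2208,0.1904,0.5542,0.4379,0.7772,0.4770,0.2700,0.5796,0.4268,0.2780,0.4892,0.5484,0.5274,0.6734,0.6201,0.7415,0.0120,0.6188,0.5935,0.3461,0.8182,0.1053,0.5830,0.6229,0.3711,0.3150,0.1413,0.6537,0.5633,0.6771,0.2103,0.6482,0.3690,0.6719,0.0078,0.4662,0.1311,0.6931,0.5321,0.0708,0.4207,0.4502,0.3742,0.0621,0.5112,0.1050
syn0005	HCEECEEHHHCEHEHCHEHHHCHECEHECCEEHEECCEHHEHEHCHECEHCEEHCCCEHHCCECHECHCHHCCCCHCECCCHCHCHCCHCHEHECCHCEH	0.3330,0.8322,0.5906,0.3840,0.4299,0.0506,0.2563,0.4551,0.7915,0.1939,0.1853,0.5472,0.0964,0.5198,0.7582,0.3090,0.7456,0.4869,0.2823,0.5395,0.3452,0.6124,0.0351,0.7524,0.0010,0.5721,0.3963,0.4470,0.0013,0.5072,0.0428,0.0761,0.6090,0.4610,0.6868,0.1495,0.5431,0.6705,0.0958,0.4500,0.7025,0.4003,0.7716,0.4867,0.4067,0.1339,0.5293,0.5631,0.2924,0.1623,0.2606,0.3334,0.4887,0.3392,0.4007,0.1913,0.4264,0.3460,0.3827,0.7809,0.3947,0.4567,0.4320,0.3496,0.2970,0.1229,0.4791,0.1954,0.0991,0.3062,0.2796,0.3401,0.5938,0.3506,0.1362,0.7179,0.1216,0.0273,0.2468,0.7262,0.0224,0.0152,0.2537,0.5406,0.4365,0.3883,0.4460,0.5074,0.6093,0.0726,0.5668,0.6999,0.1347,0.1701,0.2357,0.6934,0.1680,0.2827,0.8284,0.1822
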