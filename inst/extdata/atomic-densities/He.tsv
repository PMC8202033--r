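# element	He
# Z	2
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2.861678
r_bohr	rho_e_bohr3
1.5000e-03	3.5368e+00
1.5733e-03	3.5366e+00
1.6502e-03	3.5363e+00
1.7309e-03	3.5361e+00
1.8155e-03	3.5358e+00
1.9043e-03	3.5355e+00
1.9974e-03	3.5351e+00
2.0950e-03	3.5347e+00
2.1974e-03	3.5343e+00
2.3049e-03	3.5339e+00
2.4175e-03	3.5334e+00
2.5357e-03	3.5328e+00
2.6597e-03	3.5322e+00
2.7897e-03	3.5316e+00
2.9261e-03	3.5308e+00
3.0691e-03	3.5300e+00
3.2192e-03	3.5292e+00
3.3765e-03	3.5282e+00
3.5416e-03	3.5272e+00
3.7148e-03	3.5260e+00
3.8964e-03	3.5248e+00
4.0868e-03	3.5234e+00
4.2866e-03	3.5219e+00
4.4962e-03	3.5203e+00
4.7160e-03	3.5185e+00
4.9465e-03	3.5165e+00
5.1883e-03	3.5144e+00
5.4420e-03	3.5120e+00
5.7080e-03	3.5095e+00
5.9871e-03	3.5068e+00
6.2797e-03	3.5038e+00
6.5867e-03	3.5005e+00
6.9087e-03	3.4970e+00
7.2465e-03	3.4932e+00
7.6007e-03	3.4890e+00
7.9723e-03	3.4846e+00
8.3620e-03	3.4798e+00
8.7708e-03	3.4746e+00
9.1996e-03	3.4691e+00
9.6493e-03	3.4631e+00
1.0121e-02	3.4568e+00
1.0616e-02	3.4500e+00
1.1135e-02	3.4428e+00
1.1679e-02	3.4352e+00
1.2250e-02	3.4271e+00
1.2849e-02	3.4185e+00
1.3477e-02	3.4096e+00
1.4136e-02	3.4001e+00
1.4827e-02	3.3903e+00
1.5552e-02	3.3800e+00
1.6312e-02	3.3693e+00
1.7109e-02	3.3581e+00
1.7946e-02	3.3466e+00
1.8823e-02	3.3346e+00
1.9743e-02	3.3222e+00
2.0709e-02	3.3093e+00
2.1721e-02	3.2960e+00
2.2783e-02	3.2823e+00
2.3897e-02	3.2679e+00
2.5065e-02	3.2530e+00
2.6290e-02	3.2375e+00
2.7575e-02	3.2213e+00
2.8923e-02	3.2044e+00
3.0337e-02	3.1866e+00
3.1820e-02	3.1680e+00
3.3376e-02	3.1486e+00
3.5008e-02	3.1282e+00
3.6719e-02	3.1069e+00
3.8514e-02	3.0847e+00
4.0397e-02	3.0615e+00
4.2372e-02	3.0375e+00
4.4443e-02	3.0125e+00
4.6616e-02	2.9866e+00
4.8894e-02	2.9597e+00
5.1285e-02	2.9319e+00
5.3792e-02	2.9030e+00
5.6422e-02	2.8731e+00
5.9180e-02	2.8421e+00
6.2073e-02	2.8099e+00
6.5107e-02	2.7765e+00
6.8290e-02	2.7419e+00
7.1629e-02	2.7061e+00
7.5130e-02	2.6690e+00
7.8803e-02	2.6306e+00
8.2655e-02	2.5911e+00
8.6696e-02	2.5502e+00
9.0934e-02	2.5081e+00
9.5380e-02	2.4648e+00
1.0004e-01	2.4202e+00
1.0493e-01	2.3743e+00
1.1006e-01	2.3273e+00
1.1544e-01	2.2789e+00
1.2109e-01	2.2294e+00
1.2701e-01	2.1787e+00
1.3322e-01	2.1267e+00
1.3973e-01	2.0737e+00
1.4656e-01	2.0195e+00
1.5372e-01	1.9643e+00
1.6124e-01	1.9081e+00
1.6912e-01	1.8510e+00
1.7739e-01	1.7931e+00
1.8606e-01	1.7344e+00
1.9516e-01	1.6750e+00
2.0470e-01	1.6150e+00
2.1470e-01	1.5546e+00
2.2520e-01	1.4938e+00
2.3621e-01	1.4327e+00
2.4776e-01	1.3714e+00
2.5987e-01	1.3102e+00
2.7257e-01	1.2491e+00
2.8590e-01	1.1882e+00
2.9987e-01	1.1277e+00
3.1453e-01	1.0678e+00
3.2991e-01	1.0086e+00
3.4604e-01	9.5018e-01
3.6295e-01	8.9279e-01
3.8070e-01	8.3653e-01
3.9931e-01	7.8155e-01
4.1883e-01	7.2799e-01
4.3930e-01	6.7597e-01
4.6078e-01	6.2563e-01
4.8330e-01	5.7707e-01
5.0693e-01	5.3041e-01
5.3171e-01	4.8574e-01
5.5771e-01	4.4313e-01
5.8497e-01	4.0266e-01
6.1357e-01	3.6438e-01
6.4356e-01	3.2833e-01
6.7502e-01	2.9454e-01
7.0802e-01	2.6300e-01
7.4263e-01	2.3371e-01
7.7894e-01	2.0664e-01
8.1702e-01	1.8176e-01
8.5696e-01	1.5901e-01
8.9885e-01	1.3833e-01
9.4279e-01	1.1963e-01
9.8888e-01	1.0282e-01
1.0372e+00	8.7818e-02
1.0879e+00	7.4506e-02
1.1411e+00	6.2775e-02
1.1969e+00	5.2511e-02
1.2554e+00	4.3594e-02
1.3168e+00	3.5907e-02
1.3812e+00	2.9333e-02
1.4487e+00	2.3758e-02
1.5195e+00	1.9070e-02
1.5938e+00	1.5163e-02
1.6717e+00	1.1939e-02
1.7534e+00	9.3036e-03
1.8391e+00	7.1721e-03
1.9290e+00	5.4667e-03
2.0233e+00	4.1177e-03
2.1223e+00	3.0633e-03
2.2260e+00	2.2493e-03
2.3348e+00	1.6293e-03
2.4490e+00	1.1633e-03
2.5687e+00	8.1822e-04
2.6943e+00	5.6649e-04
2.8260e+00	3.8577e-04
2.9641e+00	2.5818e-04
3.1090e+00	1.6968e-04
3.2610e+00	1.0940e-04
3.4204e+00	6.9141e-05
3.5876e+00	4.2784e-05
3.7630e+00	2.5895e-05
3.9470e+00	1.5314e-05
4.1399e+00	8.8401e-06
4.3423e+00	4.9750e-06
4.5546e+00	2.7264e-06
4.7773e+00	1.4527e-06
5.0108e+00	7.5145e-07
5.2558e+00	3.7665e-07
5.5127e+00	1.8262e-07
5.7822e+00	8.5536e-08
6.0649e+00	3.8668e-08
6.3614e+00	1.6868e-08
6.6723e+00	7.0999e-09
6.9985e+00	2.8819e-09
7.3407e+00	1.1257e-09
7.6995e+00	4.2115e-10
8.0759e+00	1.4970e-10
8.4707e+00	4.9984e-11
8.8848e+00	1.5441e-11
9.3192e+00	4.3278e-12
9.7747e+00	1.0701e-12
1.0253e+01	2.2225e-13
1.0754e+01	3.4599e-14
1.1280e+01	2.7013e-15
1.1831e+01	1.8454e-17
1.2409e+01	5.3933e-16
1.3016e+01	6.5924e-16
1.3652e+01	4.7599e-16
1.4320e+01	2.6665e-16
1.5020e+01	1.2561e-16
1.5754e+01	5.1225e-17
1.6524e+01	1.8267e-17
1.7332e+01	5.7047e-18
1.8179e+01	1.5549e-18
1.9068e+01	3.6744e-19
2.0000e+01	7.4574e-20
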