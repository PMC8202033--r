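# element	As
# Z	33
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-2233.941781
r_bohr	rho_e_bohr3
1.5000e-03	2.2364e+04
1.5733e-03	2.2257e+04
1.6502e-03	2.2146e+04
1.7309e-03	2.2030e+04
1.8155e-03	2.1909e+04
1.9043e-03	2.1783e+04
1.9974e-03	2.1651e+04
2.0950e-03	2.1514e+04
2.1974e-03	2.1370e+04
2.3049e-03	2.1220e+04
2.4175e-03	2.1063e+04
2.5357e-03	2.0900e+04
2.6597e-03	2.0729e+04
2.7897e-03	2.0552e+04
2.9261e-03	2.0367e+04
3.0691e-03	2.0175e+04
3.2192e-03	1.9976e+04
3.3765e-03	1.9769e+04
3.5416e-03	1.9554e+04
3.7148e-03	1.9332e+04
3.8964e-03	1.9101e+04
4.0868e-03	1.8863e+04
4.2866e-03	1.8616e+04
4.4962e-03	1.8361e+04
4.7160e-03	1.8098e+04
4.9465e-03	1.7825e+04
5.1883e-03	1.7544e+04
5.4420e-03	1.7254e+04
5.7080e-03	1.6954e+04
5.9871e-03	1.6646e+04
6.2797e-03	1.6328e+04
6.5867e-03	1.6002e+04
6.9087e-03	1.5666e+04
7.2465e-03	1.5322e+04
7.6007e-03	1.4969e+04
7.9723e-03	1.4607e+04
8.3620e-03	1.4238e+04
8.7708e-03	1.3860e+04
9.1996e-03	1.3475e+04
9.6493e-03	1.3083e+04
1.0121e-02	1.2684e+04
1.0616e-02	1.2279e+04
1.1135e-02	1.1868e+04
1.1679e-02	1.1452e+04
1.2250e-02	1.1032e+04
1.2849e-02	1.0608e+04
1.3477e-02	1.0181e+04
1.4136e-02	9.7524e+03
1.4827e-02	9.3224e+03
1.5552e-02	8.8922e+03
1.6312e-02	8.4628e+03
1.7109e-02	8.0354e+03
1.7946e-02	7.6109e+03
1.8823e-02	7.1905e+03
1.9743e-02	6.7753e+03
2.0709e-02	6.3664e+03
2.1721e-02	5.9651e+03
2.2783e-02	5.5725e+03
2.3897e-02	5.1897e+03
2.5065e-02	4.8179e+03
2.6290e-02	4.4582e+03
2.7575e-02	4.1117e+03
2.8923e-02	3.7792e+03
3.0337e-02	3.4615e+03
3.1820e-02	3.1595e+03
3.3376e-02	2.8737e+03
3.5008e-02	2.6046e+03
3.6719e-02	2.3528e+03
3.8514e-02	2.1183e+03
4.0397e-02	1.9015e+03
4.2372e-02	1.7022e+03
4.4443e-02	1.5203e+03
4.6616e-02	1.3553e+03
4.8894e-02	1.2067e+03
5.1285e-02	1.0739e+03
5.3792e-02	9.5610e+02
5.6422e-02	8.5236e+02
5.9180e-02	7.6172e+02
6.2073e-02	6.8316e+02
6.5107e-02	6.1554e+02
6.8290e-02	5.5773e+02
7.1629e-02	5.0853e+02
7.5130e-02	4.6678e+02
7.8803e-02	4.3131e+02
8.2655e-02	4.0101e+02
8.6696e-02	3.7487e+02
9.0934e-02	3.5193e+02
9.5380e-02	3.3138e+02
1.0004e-01	3.1249e+02
1.0493e-01	2.9468e+02
1.1006e-01	2.7748e+02
1.1544e-01	2.6056e+02
1.2109e-01	2.4369e+02
1.2701e-01	2.2677e+02
1.3322e-01	2.0976e+02
1.3973e-01	1.9270e+02
1.4656e-01	1.7570e+02
1.5372e-01	1.5889e+02
1.6124e-01	1.4244e+02
1.6912e-01	1.2654e+02
1.7739e-01	1.1137e+02
1.8606e-01	9.7136e+01
1.9516e-01	8.3999e+01
2.0470e-01	7.2099e+01
2.1470e-01	6.1527e+01
2.2520e-01	5.2320e+01
2.3621e-01	4.4459e+01
2.4776e-01	3.7874e+01
2.5987e-01	3.2459e+01
2.7257e-01	2.8082e+01
2.8590e-01	2.4598e+01
2.9987e-01	2.1863e+01
3.1453e-01	1.9738e+01
3.2991e-01	1.8093e+01
3.4604e-01	1.6806e+01
3.6295e-01	1.5769e+01
3.8070e-01	1.4884e+01
3.9931e-01	1.4068e+01
4.1883e-01	1.3258e+01
4.3930e-01	1.2410e+01
4.6078e-01	1.1505e+01
4.8330e-01	1.0543e+01
5.0693e-01	9.5411e+00
5.3171e-01	8.5251e+00
5.5771e-01	7.5247e+00
5.8497e-01	6.5669e+00
6.1357e-01	5.6727e+00
6.4356e-01	4.8550e+00
6.7502e-01	4.1196e+00
7.0802e-01	3.4661e+00
7.4263e-01	2.8900e+00
7.7894e-01	2.3855e+00
8.1702e-01	1.9461e+00
8.5696e-01	1.5667e+00
8.9885e-01	1.2431e+00
9.4279e-01	9.7194e-01
9.8888e-01	7.5004e-01
1.0372e+00	5.7349e-01
1.0879e+00	4.3736e-01
1.1411e+00	3.3568e-01
1.1969e+00	2.6191e-01
1.2554e+00	2.0952e-01
1.3168e+00	1.7259e-01
1.3812e+00	1.4622e-01
1.4487e+00	1.2668e-01
1.5195e+00	1.1134e-01
1.5938e+00	9.8516e-02
1.6717e+00	8.7235e-02
1.7534e+00	7.6997e-02
1.8391e+00	6.7586e-02
1.9290e+00	5.8934e-02
2.0233e+00	5.1018e-02
2.1223e+00	4.3821e-02
2.2260e+00	3.7316e-02
2.3348e+00	3.1468e-02
2.4490e+00	2.6247e-02
2.5687e+00	2.1627e-02
2.6943e+00	1.7586e-02
2.8260e+00	1.4104e-02
2.9641e+00	1.1153e-02
3.1090e+00	8.6971e-03
3.2610e+00	6.6899e-03
3.4204e+00	5.0793e-03
3.5876e+00	3.8090e-03
3.7630e+00	2.8226e-03
3.9470e+00	2.0672e-03
4.1399e+00	1.4957e-03
4.3423e+00	1.0678e-03
4.5546e+00	7.5060e-04
4.7773e+00	5.1793e-04
5.0108e+00	3.4951e-04
5.2558e+00	2.2971e-04
5.5127e+00	1.4645e-04
5.7822e+00	9.0252e-05
6.0649e+00	5.3641e-05
6.3614e+00	3.0731e-05
6.6723e+00	1.7001e-05
6.9985e+00	9.1258e-06
7.3407e+00	4.7895e-06
7.6995e+00	2.4831e-06
8.0759e+00	1.2860e-06
8.4707e+00	6.7162e-07
8.8848e+00	3.5519e-07
9.3192e+00	1.8960e-07
9.7747e+00	1.0105e-07
1.0253e+01	5.2907e-08
1.0754e+01	2.6720e-08
1.1280e+01	1.2791e-08
1.1831e+01	5.7159e-09
1.2409e+01	2.3528e-09
1.3016e+01	8.8173e-10
1.3652e+01	2.9767e-10
1.4320e+01	8.9631e-11
1.5020e+01	2.3854e-11
1.5754e+01	5.5713e-12
1.6524e+01	1.1392e-12
1.7332e+01	2.0538e-13
1.8179e+01	3.3418e-14
1.9068e+01	5.1076e-15
2.0000e+01	7.5944e-16
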