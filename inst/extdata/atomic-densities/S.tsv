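# element	S
# Z	16
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-397.384654
r_bohr	rho_e_bohr3
1.5000e-03	2.5473e+03
1.5733e-03	2.5412e+03
1.6502e-03	2.5347e+03
1.7309e-03	2.5279e+03
1.8155e-03	2.5207e+03
1.9043e-03	2.5132e+03
1.9974e-03	2.5053e+03
2.0950e-03	2.4971e+03
2.1974e-03	2.4886e+03
2.3049e-03	2.4797e+03
2.4175e-03	2.4704e+03
2.5357e-03	2.4609e+03
2.6597e-03	2.4510e+03
2.7897e-03	2.4407e+03
2.9261e-03	2.4301e+03
3.0691e-03	2.4190e+03
3.2192e-03	2.4076e+03
3.3765e-03	2.3957e+03
3.5416e-03	2.3833e+03
3.7148e-03	2.3703e+03
3.8964e-03	2.3568e+03
4.0868e-03	2.3427e+03
4.2866e-03	2.3279e+03
4.4962e-03	2.3125e+03
4.7160e-03	2.2963e+03
4.9465e-03	2.2795e+03
5.1883e-03	2.2619e+03
5.4420e-03	2.2436e+03
5.7080e-03	2.2245e+03
5.9871e-03	2.2046e+03
6.2797e-03	2.1840e+03
6.5867e-03	2.1626e+03
6.9087e-03	2.1404e+03
7.2465e-03	2.1174e+03
7.6007e-03	2.0935e+03
7.9723e-03	2.0689e+03
8.3620e-03	2.0433e+03
8.7708e-03	2.0168e+03
9.1996e-03	1.9895e+03
9.6493e-03	1.9612e+03
1.0121e-02	1.9319e+03
1.0616e-02	1.9017e+03
1.1135e-02	1.8705e+03
1.1679e-02	1.8383e+03
1.2250e-02	1.8051e+03
1.2849e-02	1.7710e+03
1.3477e-02	1.7358e+03
1.4136e-02	1.6998e+03
1.4827e-02	1.6627e+03
1.5552e-02	1.6247e+03
1.6312e-02	1.5859e+03
1.7109e-02	1.5461e+03
1.7946e-02	1.5055e+03
1.8823e-02	1.4640e+03
1.9743e-02	1.4218e+03
2.0709e-02	1.3789e+03
2.1721e-02	1.3352e+03
2.2783e-02	1.2910e+03
2.3897e-02	1.2461e+03
2.5065e-02	1.2008e+03
2.6290e-02	1.1550e+03
2.7575e-02	1.1089e+03
2.8923e-02	1.0626e+03
3.0337e-02	1.0161e+03
3.1820e-02	9.6960e+02
3.3376e-02	9.2312e+02
3.5008e-02	8.7682e+02
3.6719e-02	8.3079e+02
3.8514e-02	7.8517e+02
4.0397e-02	7.4007e+02
4.2372e-02	6.9562e+02
4.4443e-02	6.5195e+02
4.6616e-02	6.0918e+02
4.8894e-02	5.6742e+02
5.1285e-02	5.2680e+02
5.3792e-02	4.8743e+02
5.6422e-02	4.4942e+02
5.9180e-02	4.1287e+02
6.2073e-02	3.7788e+02
6.5107e-02	3.4453e+02
6.8290e-02	3.1290e+02
7.1629e-02	2.8305e+02
7.5130e-02	2.5502e+02
7.8803e-02	2.2885e+02
8.2655e-02	2.0456e+02
8.6696e-02	1.8214e+02
9.0934e-02	1.6158e+02
9.5380e-02	1.4286e+02
1.0004e-01	1.2593e+02
1.0493e-01	1.1074e+02
1.1006e-01	9.7211e+01
1.1544e-01	8.5256e+01
1.2109e-01	7.4780e+01
1.2701e-01	6.5677e+01
1.3322e-01	5.7836e+01
1.3973e-01	5.1138e+01
1.4656e-01	4.5465e+01
1.5372e-01	4.0697e+01
1.6124e-01	3.6716e+01
1.6912e-01	3.3405e+01
1.7739e-01	3.0656e+01
1.8606e-01	2.8365e+01
1.9516e-01	2.6440e+01
2.0470e-01	2.4795e+01
2.1470e-01	2.3360e+01
2.2520e-01	2.2071e+01
2.3621e-01	2.0877e+01
2.4776e-01	1.9737e+01
2.5987e-01	1.8621e+01
2.7257e-01	1.7508e+01
2.8590e-01	1.6385e+01
2.9987e-01	1.5247e+01
3.1453e-01	1.4096e+01
3.2991e-01	1.2938e+01
3.4604e-01	1.1782e+01
3.6295e-01	1.0640e+01
3.8070e-01	9.5229e+00
3.9931e-01	8.4429e+00
4.1883e-01	7.4109e+00
4.3930e-01	6.4373e+00
4.6078e-01	5.5309e+00
4.8330e-01	4.6993e+00
5.0693e-01	3.9477e+00
5.3171e-01	3.2791e+00
5.5771e-01	2.6938e+00
5.8497e-01	2.1899e+00
6.1357e-01	1.7630e+00
6.4356e-01	1.4072e+00
6.7502e-01	1.1155e+00
7.0802e-01	8.8051e-01
7.4263e-01	6.9457e-01
7.7894e-01	5.5041e-01
8.1702e-01	4.4109e-01
8.5696e-01	3.6018e-01
8.9885e-01	3.0173e-01
9.4279e-01	2.6041e-01
9.8888e-01	2.3157e-01
1.0372e+00	2.1129e-01
1.0879e+00	1.9645e-01
1.1411e+00	1.8470e-01
1.1969e+00	1.7438e-01
1.2554e+00	1.6442e-01
1.3168e+00	1.5422e-01
1.3812e+00	1.4350e-01
1.4487e+00	1.3220e-01
1.5195e+00	1.2044e-01
1.5938e+00	1.0840e-01
1.6717e+00	9.6328e-02
1.7534e+00	8.4486e-02
1.8391e+00	7.3121e-02
1.9290e+00	6.2451e-02
2.0233e+00	5.2647e-02
2.1223e+00	4.3820e-02
2.2260e+00	3.6026e-02
2.3348e+00	2.9267e-02
2.4490e+00	2.3503e-02
2.5687e+00	1.8663e-02
2.6943e+00	1.4655e-02
2.8260e+00	1.1378e-02
2.9641e+00	8.7333e-03
3.1090e+00	6.6235e-03
3.2610e+00	4.9618e-03
3.4204e+00	3.6704e-03
3.5876e+00	2.6817e-03
3.7630e+00	1.9364e-03
3.9470e+00	1.3837e-03
4.1399e+00	9.8023e-04
4.3423e+00	6.8987e-04
4.5546e+00	4.8323e-04
4.7773e+00	3.3728e-04
5.0108e+00	2.3459e-04
5.2558e+00	1.6243e-04
5.5127e+00	1.1172e-04
5.7822e+00	7.6168e-05
6.0649e+00	5.1362e-05
6.3614e+00	3.4218e-05
6.6723e+00	2.2523e-05
6.9985e+00	1.4664e-05
7.3407e+00	9.4552e-06
7.6995e+00	6.0423e-06
8.0759e+00	3.8226e-06
8.4707e+00	2.3856e-06
8.8848e+00	1.4599e-06
9.3192e+00	8.6907e-07
9.7747e+00	4.9867e-07
1.0253e+01	2.7310e-07
1.0754e+01	1.4132e-07
1.1280e+01	6.8413e-08
1.1831e+01	3.0677e-08
1.2409e+01	1.2616e-08
1.3016e+01	4.7105e-09
1.3652e+01	1.5803e-09
1.4320e+01	4.7109e-10
1.5020e+01	1.2334e-10
1.5754e+01	2.8013e-11
1.6524e+01	5.4494e-12
1.7332e+01	8.9716e-13
1.8179e+01	1.2395e-13
1.9068e+01	1.4399e-14
2.0000e+01	1.4451e-15
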