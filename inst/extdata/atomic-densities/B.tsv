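# element	B
# Z	5
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-24.414922
r_bohr	rho_e_bohr3
1.5000e-03	7.0670e+01
1.5733e-03	7.0645e+01
1.6502e-03	7.0618e+01
1.7309e-03	7.0588e+01
1.8155e-03	7.0555e+01
1.9043e-03	7.0520e+01
1.9974e-03	7.0481e+01
2.0950e-03	7.0438e+01
2.1974e-03	7.0392e+01
2.3049e-03	7.0342e+01
2.4175e-03	7.0287e+01
2.5357e-03	7.0227e+01
2.6597e-03	7.0162e+01
2.7897e-03	7.0092e+01
2.9261e-03	7.0016e+01
3.0691e-03	6.9933e+01
3.2192e-03	6.9844e+01
3.3765e-03	6.9748e+01
3.5416e-03	6.9645e+01
3.7148e-03	6.9534e+01
3.8964e-03	6.9415e+01
4.0868e-03	6.9288e+01
4.2866e-03	6.9152e+01
4.4962e-03	6.9007e+01
4.7160e-03	6.8853e+01
4.9465e-03	6.8690e+01
5.1883e-03	6.8518e+01
5.4420e-03	6.8337e+01
5.7080e-03	6.8146e+01
5.9871e-03	6.7946e+01
6.2797e-03	6.7738e+01
6.5867e-03	6.7520e+01
6.9087e-03	6.7293e+01
7.2465e-03	6.7058e+01
7.6007e-03	6.6814e+01
7.9723e-03	6.6561e+01
8.3620e-03	6.6299e+01
8.7708e-03	6.6028e+01
9.1996e-03	6.5747e+01
9.6493e-03	6.5455e+01
1.0121e-02	6.5152e+01
1.0616e-02	6.4836e+01
1.1135e-02	6.4508e+01
1.1679e-02	6.4164e+01
1.2250e-02	6.3805e+01
1.2849e-02	6.3429e+01
1.3477e-02	6.3036e+01
1.4136e-02	6.2625e+01
1.4827e-02	6.2194e+01
1.5552e-02	6.1745e+01
1.6312e-02	6.1276e+01
1.7109e-02	6.0788e+01
1.7946e-02	6.0280e+01
1.8823e-02	5.9753e+01
1.9743e-02	5.9205e+01
2.0709e-02	5.8638e+01
2.1721e-02	5.8049e+01
2.2783e-02	5.7439e+01
2.3897e-02	5.6808e+01
2.5065e-02	5.6153e+01
2.6290e-02	5.5475e+01
2.7575e-02	5.4772e+01
2.8923e-02	5.4045e+01
3.0337e-02	5.3291e+01
3.1820e-02	5.2513e+01
3.3376e-02	5.1708e+01
3.5008e-02	5.0876e+01
3.6719e-02	5.0019e+01
3.8514e-02	4.9135e+01
4.0397e-02	4.8226e+01
4.2372e-02	4.7291e+01
4.4443e-02	4.6330e+01
4.6616e-02	4.5344e+01
4.8894e-02	4.4333e+01
5.1285e-02	4.3298e+01
5.3792e-02	4.2238e+01
5.6422e-02	4.1156e+01
5.9180e-02	4.0051e+01
6.2073e-02	3.8924e+01
6.5107e-02	3.7777e+01
6.8290e-02	3.6611e+01
7.1629e-02	3.5427e+01
7.5130e-02	3.4228e+01
7.8803e-02	3.3014e+01
8.2655e-02	3.1788e+01
8.6696e-02	3.0552e+01
9.0934e-02	2.9309e+01
9.5380e-02	2.8060e+01
1.0004e-01	2.6809e+01
1.0493e-01	2.5558e+01
1.1006e-01	2.4309e+01
1.1544e-01	2.3067e+01
1.2109e-01	2.1833e+01
1.2701e-01	2.0612e+01
1.3322e-01	1.9405e+01
1.3973e-01	1.8217e+01
1.4656e-01	1.7050e+01
1.5372e-01	1.5908e+01
1.6124e-01	1.4793e+01
1.6912e-01	1.3710e+01
1.7739e-01	1.2660e+01
1.8606e-01	1.1647e+01
1.9516e-01	1.0672e+01
2.0470e-01	9.7389e+00
2.1470e-01	8.8490e+00
2.2520e-01	8.0042e+00
2.3621e-01	7.2060e+00
2.4776e-01	6.4554e+00
2.5987e-01	5.7531e+00
2.7257e-01	5.0997e+00
2.8590e-01	4.4951e+00
2.9987e-01	3.9389e+00
3.1453e-01	3.4305e+00
3.2991e-01	2.9688e+00
3.4604e-01	2.5524e+00
3.6295e-01	2.1796e+00
3.8070e-01	1.8483e+00
3.9931e-01	1.5562e+00
4.1883e-01	1.3010e+00
4.3930e-01	1.0800e+00
4.6078e-01	8.9050e-01
4.8330e-01	7.2963e-01
5.0693e-01	5.9458e-01
5.3171e-01	4.8254e-01
5.5771e-01	3.9073e-01
5.8497e-01	3.1653e-01
6.1357e-01	2.5743e-01
6.4356e-01	2.1107e-01
6.7502e-01	1.7533e-01
7.0802e-01	1.4823e-01
7.4263e-01	1.2805e-01
7.7894e-01	1.1326e-01
8.1702e-01	1.0257e-01
8.5696e-01	9.4858e-02
8.9885e-01	8.9234e-02
9.4279e-01	8.4972e-02
9.8888e-01	8.1508e-02
1.0372e+00	7.8419e-02
1.0879e+00	7.5404e-02
1.1411e+00	7.2265e-02
1.1969e+00	6.8888e-02
1.2554e+00	6.5223e-02
1.3168e+00	6.1273e-02
1.3812e+00	5.7073e-02
1.4487e+00	5.2686e-02
1.5195e+00	4.8186e-02
1.5938e+00	4.3653e-02
1.6717e+00	3.9169e-02
1.7534e+00	3.4806e-02
1.8391e+00	3.0630e-02
1.9290e+00	2.6694e-02
2.0233e+00	2.3038e-02
2.1223e+00	1.9690e-02
2.2260e+00	1.6666e-02
2.3348e+00	1.3971e-02
2.4490e+00	1.1599e-02
2.5687e+00	9.5399e-03
2.6943e+00	7.7731e-03
2.8260e+00	6.2758e-03
2.9641e+00	5.0218e-03
3.1090e+00	3.9838e-03
3.2610e+00	3.1343e-03
3.4204e+00	2.4467e-03
3.5876e+00	1.8961e-03
3.7630e+00	1.4596e-03
3.9470e+00	1.1168e-03
4.1399e+00	8.5006e-04
4.3423e+00	6.4409e-04
4.5546e+00	4.8615e-04
4.7773e+00	3.6572e-04
5.0108e+00	2.7432e-04
5.2558e+00	2.0516e-04
5.5127e+00	1.5291e-04
5.7822e+00	1.1346e-04
6.0649e+00	8.3673e-05
6.3614e+00	6.1186e-05
6.6723e+00	4.4237e-05
6.9985e+00	3.1521e-05
7.3407e+00	2.2057e-05
7.6995e+00	1.5103e-05
8.0759e+00	1.0081e-05
8.4707e+00	6.5316e-06
8.8848e+00	4.0900e-06
9.3192e+00	2.4625e-06
9.7747e+00	1.4172e-06
1.0253e+01	7.7450e-07
1.0754e+01	3.9896e-07
1.1280e+01	1.9213e-07
1.1831e+01	8.5743e-08
1.2409e+01	3.5126e-08
1.3016e+01	1.3077e-08
1.3652e+01	4.3771e-09
1.4320e+01	1.3023e-09
1.5020e+01	3.4018e-10
1.5754e+01	7.6998e-11
1.6524e+01	1.4888e-11
1.7332e+01	2.4223e-12
1.8179e+01	3.2653e-13
1.9068e+01	3.5957e-14
2.0000e+01	3.2106e-15
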