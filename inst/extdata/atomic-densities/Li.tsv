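# element	Li
# Z	3
# provenance	hirshfeldr-atomic-uhf-even-tempered
# scf_energy_hartree	-7.432744
r_bohr	rho_e_bohr3
1.5000e-03	1.3574e+01
1.5733e-03	1.3573e+01
1.6502e-03	1.3571e+01
1.7309e-03	1.3568e+01
1.8155e-03	1.3566e+01
1.9043e-03	1.3563e+01
1.9974e-03	1.3561e+01
2.0950e-03	1.3557e+01
2.1974e-03	1.3554e+01
2.3049e-03	1.3550e+01
2.4175e-03	1.3546e+01
2.5357e-03	1.3541e+01
2.6597e-03	1.3536e+01
2.7897e-03	1.3531e+01
2.9261e-03	1.3525e+01
3.0691e-03	1.3519e+01
3.2192e-03	1.3511e+01
3.3765e-03	1.3504e+01
3.5416e-03	1.3495e+01
3.7148e-03	1.3486e+01
3.8964e-03	1.3476e+01
4.0868e-03	1.3465e+01
4.2866e-03	1.3453e+01
4.4962e-03	1.3440e+01
4.7160e-03	1.3426e+01
4.9465e-03	1.3411e+01
5.1883e-03	1.3395e+01
5.4420e-03	1.3377e+01
5.7080e-03	1.3358e+01
5.9871e-03	1.3338e+01
6.2797e-03	1.3316e+01
6.5867e-03	1.3293e+01
6.9087e-03	1.3268e+01
7.2465e-03	1.3241e+01
7.6007e-03	1.3213e+01
7.9723e-03	1.3182e+01
8.3620e-03	1.3151e+01
8.7708e-03	1.3117e+01
9.1996e-03	1.3082e+01
9.6493e-03	1.3045e+01
1.0121e-02	1.3006e+01
1.0616e-02	1.2965e+01
1.1135e-02	1.2923e+01
1.1679e-02	1.2880e+01
1.2250e-02	1.2834e+01
1.2849e-02	1.2787e+01
1.3477e-02	1.2738e+01
1.4136e-02	1.2688e+01
1.4827e-02	1.2636e+01
1.5552e-02	1.2582e+01
1.6312e-02	1.2525e+01
1.7109e-02	1.2467e+01
1.7946e-02	1.2406e+01
1.8823e-02	1.2342e+01
1.9743e-02	1.2275e+01
2.0709e-02	1.2206e+01
2.1721e-02	1.2133e+01
2.2783e-02	1.2056e+01
2.3897e-02	1.1976e+01
2.5065e-02	1.1893e+01
2.6290e-02	1.1805e+01
2.7575e-02	1.1715e+01
2.8923e-02	1.1620e+01
3.0337e-02	1.1522e+01
3.1820e-02	1.1420e+01
3.3376e-02	1.1315e+01
3.5008e-02	1.1205e+01
3.6719e-02	1.1092e+01
3.8514e-02	1.0975e+01
4.0397e-02	1.0853e+01
4.2372e-02	1.0726e+01
4.4443e-02	1.0596e+01
4.6616e-02	1.0460e+01
4.8894e-02	1.0320e+01
5.1285e-02	1.0174e+01
5.3792e-02	1.0024e+01
5.6422e-02	9.8689e+00
5.9180e-02	9.7088e+00
6.2073e-02	9.5438e+00
6.5107e-02	9.3740e+00
6.8290e-02	9.1993e+00
7.1629e-02	9.0197e+00
7.5130e-02	8.8354e+00
7.8803e-02	8.6463e+00
8.2655e-02	8.4525e+00
8.6696e-02	8.2541e+00
9.0934e-02	8.0512e+00
9.5380e-02	7.8439e+00
1.0004e-01	7.6324e+00
1.0493e-01	7.4169e+00
1.1006e-01	7.1976e+00
1.1544e-01	6.9749e+00
1.2109e-01	6.7490e+00
1.2701e-01	6.5202e+00
1.3322e-01	6.2889e+00
1.3973e-01	6.0556e+00
1.4656e-01	5.8205e+00
1.5372e-01	5.5841e+00
1.6124e-01	5.3469e+00
1.6912e-01	5.1094e+00
1.7739e-01	4.8721e+00
1.8606e-01	4.6354e+00
1.9516e-01	4.4000e+00
2.0470e-01	4.1665e+00
2.1470e-01	3.9354e+00
2.2520e-01	3.7072e+00
2.3621e-01	3.4827e+00
2.4776e-01	3.2623e+00
2.5987e-01	3.0467e+00
2.7257e-01	2.8364e+00
2.8590e-01	2.6320e+00
2.9987e-01	2.4340e+00
3.1453e-01	2.2429e+00
3.2991e-01	2.0591e+00
3.4604e-01	1.8830e+00
3.6295e-01	1.7150e+00
3.8070e-01	1.5553e+00
3.9931e-01	1.4044e+00
4.1883e-01	1.2622e+00
4.3930e-01	1.1289e+00
4.6078e-01	1.0047e+00
4.8330e-01	8.8945e-01
5.0693e-01	7.8312e-01
5.3171e-01	6.8556e-01
5.5771e-01	5.9659e-01
5.8497e-01	5.1593e-01
6.1357e-01	4.4328e-01
6.4356e-01	3.7829e-01
6.7502e-01	3.2055e-01
7.0802e-01	2.6963e-01
7.4263e-01	2.2508e-01
7.7894e-01	1.8640e-01
8.1702e-01	1.5311e-01
8.5696e-01	1.2471e-01
8.9885e-01	1.0072e-01
9.4279e-01	8.0653e-02
9.8888e-01	6.4042e-02
1.0372e+00	5.0446e-02
1.0879e+00	3.9450e-02
1.1411e+00	3.0670e-02
1.1969e+00	2.3755e-02
1.2554e+00	1.8387e-02
1.3168e+00	1.4285e-02
1.3812e+00	1.1202e-02
1.4487e+00	8.9269e-03
1.5195e+00	7.2783e-03
1.5938e+00	6.1060e-03
1.6717e+00	5.2869e-03
1.7534e+00	4.7218e-03
1.8391e+00	4.3326e-03
1.9290e+00	4.0590e-03
2.0233e+00	3.8561e-03
2.1223e+00	3.6912e-03
2.2260e+00	3.5415e-03
2.3348e+00	3.3921e-03
2.4490e+00	3.2341e-03
2.5687e+00	3.0631e-03
2.6943e+00	2.8779e-03
2.8260e+00	2.6796e-03
2.9641e+00	2.4708e-03
3.1090e+00	2.2550e-03
3.2610e+00	2.0360e-03
3.4204e+00	1.8180e-03
3.5876e+00	1.6046e-03
3.7630e+00	1.3996e-03
3.9470e+00	1.2057e-03
4.1399e+00	1.0255e-03
4.3423e+00	8.6081e-04
4.5546e+00	7.1270e-04
4.7773e+00	5.8174e-04
5.0108e+00	4.6788e-04
5.2558e+00	3.7058e-04
5.5127e+00	2.8888e-04
5.7822e+00	2.2149e-04
6.0649e+00	1.6693e-04
6.3614e+00	1.2357e-04
6.6723e+00	8.9782e-05
6.9985e+00	6.3971e-05
7.3407e+00	4.4656e-05
7.6995e+00	3.0508e-05
8.0759e+00	2.0374e-05
8.4707e+00	1.3282e-05
8.8848e+00	8.4410e-06
9.3192e+00	5.2212e-06
9.7747e+00	3.1381e-06
1.0253e+01	1.8292e-06
1.0754e+01	1.0318e-06
1.1280e+01	5.6171e-07
1.1831e+01	2.9412e-07
1.2409e+01	1.4748e-07
1.3016e+01	7.0436e-08
1.3652e+01	3.1826e-08
1.4320e+01	1.3498e-08
1.5020e+01	5.3251e-09
1.5754e+01	1.9345e-09
1.6524e+01	6.4017e-10
1.7332e+01	1.9072e-10
1.8179e+01	5.0526e-11
1.9068e+01	1.1746e-11
2.0000e+01	2.3629e-12
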