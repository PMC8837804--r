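# Elemental mass attenuation coefficients, total with coherent scatter
# columns: element symbol, Z, atomic mass, energy [keV], mu/rho [cm^2/g]
# absorption edges appear as duplicated energies (below-edge row first)
element	Z	A	energy_keV	mu_rho
Al	13	26.982	5.0	206
Al	13	26.982	6.0	119.7
Al	13	26.982	8.0	50.85
Al	13	26.982	10.0	26.23
Al	13	26.982	15.0	7.955
Al	13	26.982	20.0	3.441
Al	13	26.982	30.0	1.128
Al	13	26.982	40.0	0.5685
Al	13	26.982	50.0	0.3681
Al	13	26.982	60.0	0.2778
Al	13	26.982	80.0	0.2018
Be	4	9.012	5.0	4.055
Be	4	9.012	6.0	2.406
Be	4	9.012	8.0	1.106
Be	4	9.012	10.0	0.6466
Be	4	9.012	15.0	0.307
Be	4	9.012	20.0	0.2251
Be	4	9.012	30.0	0.1792
Be	4	9.012	40.0	0.164
Be	4	9.012	50.0	0.1554
Be	4	9.012	60.0	0.1493
Be	4	9.012	80.0	0.1401
C	6	12.011	5.0	19
C	6	12.011	6.0	10.86
C	6	12.011	8.0	4.555
C	6	12.011	10.0	2.373
C	6	12.011	15.0	0.8071
C	6	12.011	20.0	0.442
C	6	12.011	30.0	0.2562
C	6	12.011	40.0	0.2076
C	6	12.011	50.0	0.1871
C	6	12.011	60.0	0.1753
C	6	12.011	80.0	0.161
Ca	20	40.078	5.0	575.7
Ca	20	40.078	6.0	356.7
Ca	20	40.078	8.0	167.7
Ca	20	40.078	10.0	93.41
Ca	20	40.078	15.0	32.33
Ca	20	40.078	20.0	14.46
Ca	20	40.078	30.0	4.953
Ca	20	40.078	40.0	2.217
Ca	20	40.078	50.0	1.216
Ca	20	40.078	60.0	0.7894
Ca	20	40.078	80.0	0.4124
Cl	17	35.450	5.0	386.8
Cl	17	35.450	6.0	233.2
Cl	17	35.450	8.0	105
Cl	17	35.450	10.0	56.56
Cl	17	35.450	15.0	18.46
Cl	17	35.450	20.0	8.104
Cl	17	35.450	30.0	2.671
Cl	17	35.450	40.0	1.227
Cl	17	35.450	50.0	0.705
Cl	17	35.450	60.0	0.4778
Cl	17	35.450	80.0	0.2837
Cs	55	132.905	5.0	1597
Cs	55	132.905	6.0	958.2
Cs	55	132.905	8.0	428.2
Cs	55	132.905	10.0	229.2
Cs	55	132.905	15.0	77.11
Cs	55	132.905	20.0	35.66
Cs	55	132.905	30.0	12
Cs	55	132.905	36.0	7.356
Cs	55	132.905	36.0	40.41
Cs	55	132.905	40.0	30.75
Cs	55	132.905	50.0	17.18
Cs	55	132.905	60.0	10.61
Cs	55	132.905	80.0	4.917
Fe	26	55.845	5.0	139.8
Fe	26	55.845	6.0	84.84
Fe	26	55.845	7.1	53.19
Fe	26	55.845	7.1	407.6
Fe	26	55.845	8.0	305.6
Fe	26	55.845	10.0	170.6
Fe	26	55.845	15.0	57.08
Fe	26	55.845	20.0	25.68
Fe	26	55.845	30.0	8.176
Fe	26	55.845	40.0	3.629
Fe	26	55.845	50.0	1.958
Fe	26	55.845	60.0	1.205
Fe	26	55.845	80.0	0.5952
H	1	1.008	5.0	0.4116
H	1	1.008	6.0	0.4005
H	1	1.008	8.0	0.3914
H	1	1.008	10.0	0.3854
H	1	1.008	15.0	0.3764
H	1	1.008	20.0	0.3695
H	1	1.008	30.0	0.357
H	1	1.008	40.0	0.3458
H	1	1.008	50.0	0.3355
H	1	1.008	60.0	0.326
H	1	1.008	80.0	0.3091
I	53	126.904	5.0	1128
I	53	126.904	6.0	677.2
I	53	126.904	8.0	302.6
I	53	126.904	10.0	162
I	53	126.904	15.0	55.12
I	53	126.904	20.0	25.43
I	53	126.904	30.0	8.561
I	53	126.904	33.2	6.521
I	53	126.904	33.2	35.82
I	53	126.904	40.0	22.1
I	53	126.904	50.0	12.32
I	53	126.904	60.0	7.579
I	53	126.904	80.0	3.51
K	19	39.098	5.0	500.7
K	19	39.098	6.0	307.6
K	19	39.098	8.0	142.6
K	19	39.098	10.0	78.62
K	19	39.098	15.0	26.71
K	19	39.098	20.0	11.87
K	19	39.098	30.0	4.012
K	19	39.098	40.0	1.807
K	19	39.098	50.0	1.004
K	19	39.098	60.0	0.659
K	19	39.098	80.0	0.3579
Mg	12	24.305	5.0	165.6
Mg	12	24.305	6.0	95.92
Mg	12	24.305	8.0	40.58
Mg	12	24.305	10.0	20.87
Mg	12	24.305	15.0	6.316
Mg	12	24.305	20.0	2.748
Mg	12	24.305	30.0	0.9278
Mg	12	24.305	40.0	0.4876
Mg	12	24.305	50.0	0.3291
Mg	12	24.305	60.0	0.2571
Mg	12	24.305	80.0	0.1952
N	7	14.007	5.0	31.89
N	7	14.007	6.0	18.19
N	7	14.007	8.0	7.561
N	7	14.007	10.0	3.879
N	7	14.007	15.0	1.236
N	7	14.007	20.0	0.6178
N	7	14.007	30.0	0.3066
N	7	14.007	40.0	0.2288
N	7	14.007	50.0	0.198
N	7	14.007	60.0	0.1817
N	7	14.007	80.0	0.1639
Na	11	22.990	5.0	123.3
Na	11	22.990	6.0	71.19
Na	11	22.990	8.0	29.98
Na	11	22.990	10.0	15.38
Na	11	22.990	15.0	4.649
Na	11	22.990	20.0	2.042
Na	11	22.990	30.0	0.7169
Na	11	22.990	40.0	0.3964
Na	11	22.990	50.0	0.2803
Na	11	22.990	60.0	0.2269
Na	11	22.990	80.0	0.1797
O	8	15.999	5.0	49.15
O	8	15.999	6.0	28.07
O	8	15.999	8.0	11.66
O	8	15.999	10.0	5.952
O	8	15.999	15.0	1.836
O	8	15.999	20.0	0.8651
O	8	15.999	30.0	0.3779
O	8	15.999	40.0	0.2585
O	8	15.999	50.0	0.2132
O	8	15.999	60.0	0.1907
O	8	15.999	80.0	0.1678
P	15	30.974	5.0	296.5
P	15	30.974	6.0	175
P	15	30.974	8.0	76.21
P	15	30.974	10.0	40.04
P	15	30.974	15.0	12.51
P	15	30.974	20.0	5.427
P	15	30.974	30.0	1.754
P	15	30.974	40.0	0.8345
P	15	30.974	50.0	0.5046
P	15	30.974	60.0	0.3583
P	15	30.974	80.0	0.2358
S	16	32.060	5.0	352.2
S	16	32.060	6.0	210.2
S	16	32.060	8.0	93.1
S	16	32.060	10.0	49.55
S	16	32.060	15.0	15.83
S	16	32.060	20.0	6.908
S	16	32.060	30.0	2.252
S	16	32.060	40.0	1.05
S	16	32.060	50.0	0.6175
S	16	32.060	60.0	0.4275
S	16	32.060	80.0	0.2669
Si	14	28.085	5.0	262.2
Si	14	28.085	6.0	153
Si	14	28.085	8.0	65.41
Si	14	28.085	10.0	33.89
Si	14	28.085	15.0	10.34
Si	14	28.085	20.0	4.464
Si	14	28.085	30.0	1.436
Si	14	28.085	40.0	0.7012
Si	14	28.085	50.0	0.4385
Si	14	28.085	60.0	0.3207
Si	14	28.085	80.0	0.2228
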