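# Reference material library: tissues (ICRU-style compositions) and
# detector/filter materials. Mass fractions normalized to 1.
name	density_g_cm3	composition
air	0.0012	N:0.755000,O:0.245000
water	1.0	H:0.111900,O:0.888100
soft_tissue	1.03	H:0.105000,C:0.256000,N:0.027000,O:0.602000,Na:0.001000,P:0.002000,S:0.003000,Cl:0.002000,K:0.002000
muscle	1.05	H:0.102000,C:0.143000,N:0.034000,O:0.710000,Na:0.001000,P:0.002000,S:0.003000,Cl:0.001000,K:0.004000
adipose	0.95	H:0.114000,C:0.598000,N:0.007000,O:0.278000,Na:0.001000,S:0.001000,Cl:0.001000
skin	1.09	H:0.100000,C:0.204000,N:0.042000,O:0.645000,Na:0.002000,P:0.001000,S:0.002000,Cl:0.003000,K:0.001000
cortical_bone	1.92	H:0.034000,C:0.155000,N:0.042000,O:0.435000,Na:0.001000,Mg:0.002000,P:0.103000,S:0.003000,Ca:0.225000
spongiosa	1.18	H:0.085000,C:0.404000,N:0.058000,O:0.367000,Na:0.001000,Cl:0.002000,K:0.001000,P:0.034000,S:0.002000,Mg:0.001000,Ca:0.044000,Fe:0.001000
brain	1.04	H:0.107000,C:0.145000,N:0.022000,O:0.712000,Na:0.002000,P:0.004000,S:0.002000,Cl:0.003000,K:0.003000
lung	0.26	H:0.103000,C:0.105000,N:0.031000,O:0.749000,Na:0.002000,P:0.002000,S:0.003000,Cl:0.003000,K:0.002000
liver	1.06	H:0.102000,C:0.139000,N:0.030000,O:0.716000,Na:0.002000,P:0.003000,S:0.003000,Cl:0.002000,K:0.003000
kidney	1.05	H:0.103000,C:0.132000,N:0.030000,O:0.724000,Na:0.002000,P:0.002000,S:0.002000,Cl:0.002000,K:0.002000,Ca:0.001000
heart	1.05	H:0.104000,C:0.139000,N:0.029000,O:0.718000,Na:0.001000,P:0.002000,S:0.002000,Cl:0.002000,K:0.003000
blood	1.06	H:0.102000,C:0.110000,N:0.033000,O:0.745000,Na:0.001000,P:0.001000,S:0.002000,Cl:0.003000,K:0.002000,Fe:0.001000
cartilage	1.1	H:0.096000,C:0.099000,N:0.022000,O:0.744000,Na:0.005000,P:0.022000,S:0.009000,Cl:0.003000
intestine	1.03	H:0.106000,C:0.115000,N:0.022000,O:0.751000,Na:0.001000,P:0.001000,S:0.001000,Cl:0.002000,K:0.001000
beryllium	1.848	Be:1.000000
aluminum	2.699	Al:1.000000
carbon	1.7	C:1.000000
csi	4.51	Cs:0.511500,I:0.488500
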