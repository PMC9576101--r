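# Mass attenuation coefficients: skeletal_muscle
# Provenance: ICRU-44 skeletal muscle; mixture-rule compilation (~1-2% of published)
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 1.05 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	5.3540
15	1.6780
20	0.8103
30	0.3744
40	0.2667
50	0.2253
60	0.2043
80	0.1821
100	0.1692
150	0.1491
200	0.1358
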