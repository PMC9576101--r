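# Mass attenuation coefficients: blood
# Provenance: ICRU-44 whole blood; mixture-rule compilation (~1-2% of published)
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 1.06 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	5.5210
15	1.7240
20	0.8286
30	0.3794
40	0.2687
50	0.2262
60	0.2048
80	0.1823
100	0.1693
150	0.1492
200	0.1358
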