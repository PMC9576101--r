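# Mass attenuation coefficients: adipose
# Provenance: ICRU-44 adipose tissue; mixture-rule compilation (~1-2% of published)
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 0.95 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	3.4970
15	1.1710
20	0.6091
30	0.3208
40	0.2466
50	0.2163
60	0.2001
80	0.1815
100	0.1697
150	0.1504
200	0.1370
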