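# Mass attenuation coefficients: water
# Provenance: liquid water; NIST standard grid values
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 1 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	5.3290
15	1.6730
20	0.8096
30	0.3756
40	0.2683
50	0.2269
60	0.2059
80	0.1837
100	0.1707
150	0.1505
200	0.1370
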