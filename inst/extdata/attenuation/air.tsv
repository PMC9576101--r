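# Mass attenuation coefficients: air
# Provenance: dry air, sea level; NIST standard grid values
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 0.0012 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	5.1200
15	1.6140
20	0.7779
30	0.3538
40	0.2485
50	0.2080
60	0.1875
80	0.1662
100	0.1541
150	0.1356
200	0.1233
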