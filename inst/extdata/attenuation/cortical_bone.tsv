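# Mass attenuation coefficients: cortical_bone
# Provenance: ICRU-44 cortical bone; standard published grid values
# Compiled for this package; see package documentation for the mixture rule.
# Reference mass density rho_ref = 1.92 g/cm^3 (ICRU-44 nominal)
# Columns: energy_kev <tab> mass_attenuation_cm2_g
10	28.5100
15	9.0320
20	4.0010
30	1.3310
40	0.6655
50	0.4242
60	0.3148
80	0.2229
100	0.1860
150	0.1480
200	0.1309
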