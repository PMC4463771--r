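element	monoisotopic_mass
C	12.000000000
H	1.007825030
N	14.003074010
O	15.994914620
P	30.973762000
e	0.000548580
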