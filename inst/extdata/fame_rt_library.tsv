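fame	carbons	doubleBonds	rt_min
FA 10:0	10	0	8.60
FA 12:0	12	0	12.90
FA 14:0	14	0	17.20
FA 14:1	14	1	18.05
FA 15:0	15	0	19.30
FA 16:0	16	0	21.40
FA 16:1	16	1	22.15
FA 17:0	17	0	23.30
FA 18:0	18	0	25.20
FA 18:1n-9c	18	1	25.85
FA 18:2n6c	18	2	26.95
FA 18:3n3c	18	3	28.20
FA 20:0	20	0	29.80
FA 20:1	20	1	30.45
FA 20:3n3c	20	3	32.00
FA 20:4	20	4	32.70
FA 22:5	22	5	36.80
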