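haplogroup	Volga-Oka Region	Ryazan Russians	Mordvins	Erzya	Moksha	Shoksha
n	913	280	633	317	251	65
R1a (total)	47.9	56.4	44.1	55.5	30.3	41.5
R1a-CTS1211	35	35	35.1	423	24.7	40
R1a-Z92	6.2	11.8	3.8	4.1	4	1.5
R1a-PF6202	3.4	7.9	1.4	2.5	0.4	0
R1a-Z93	3.2	1.8	3.8	6.6	1.2	0
N3 (total)	15	11.4	16.6	13.2	13.5	44.6
N3a1-B211	7.2	0.4	10.3	8.8	8.4	24.6
N3a3-CTS10760	4.2	6.4	3.2	0.6	4.8	9.2
N3a4-Z1936	3.6	4.6	3.2	3.8	0.4	10.8
E-M78	6.6	2.5	8.4	2.8	16.7	3.1
I2-P37.2	3.3	9.3	0.6	0.9	0.4	0
J2-M172	6.1	0.7	8.5	4.7	15.1	1.5
I1-M253	4.3	3.6	4.6	8.5	0.8	0
R1b-M269	4.3	2.1	5.2	3.5	7.2	6.2
G2-P303	4.4	1.8	5.5	3.8	9.2	0
Other	8.2	12.1	6.5	6.9	6.8	3.1
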