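Protein.ID	Gene.name	Ratio.M.L.rep1	Ratio.M.L.rep2	Ratio.H.L.rep1	Ratio.H.L.rep2
P01	GNA	0.8	1.2	0.9	1.1
P02	GNB	1.1	0.9	1.3	0.7
P03	GNC	1.5	1.4	1.2	1.6
P04	GND	0.7	0.6	0.8	0.5
P05	GNE	2.2	1.8	2.5	2.1
P06	GNF	1.0		1.1	NaN
P07	GNG	4.5	5.2	6.1	4.9
P08	GNH	0.95	1.05	1.0	1.0
P09	GNI	1.3	1.1	1.4	1.2
P10	GNJ	8.0	7.5	9.2	8.8
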