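Protein.ID	Gene.name	Ratio.M.L.rep1	Ratio.H.L.rep1
Q01	GA	1.0	1.1
Q02	GB	2.0	0.9
Q03	GC	0.5	1.4
Q04	GD	-1	1.0
Q05	GE	1.2	1.3
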