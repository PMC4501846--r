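Protein.ID	Residue	Position	Modification	Localization.prob	Score	PEP	Peptide.Cterm	Ratio.M.L.rep1	Ratio.H.L.rep1
S01	S	12	phospho	0.75	40	0.01	FALSE	2.5	1.2
S02	T	34	phospho	0.74	95	0.001	FALSE	1.1	1.0
S03	Y	56	phospho	0.99	85	0.002	FALSE	4.0	2.0
S04	S	78	phospho	0.88	120	0.02	FALSE	0.4	0.5
S05	Y	90	phospho	0.95	60	0.005	FALSE	3.0	3.1
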