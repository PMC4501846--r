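Protein.ID	Residue	Position	Modification	Localization.prob	Score	PEP	Peptide.Cterm	Ratio.M.L.rep1	Ratio.H.L.rep1
U01	K	10	diGly	0.9	80	0.001	FALSE	2.2	2.4
U02	K	20	diGly	0.95	90	0.002	TRUE	3.0	1.0
U03	K	30	diGly	0.85	70	0.003	FALSE	1.0	1.1
U04	K	40	diGly	0.8	60	0.004	FALSE	0.4	0.6
U05	K	50	diGly	0.99	100	0.005	TRUE	2.1	2.0
U06	K	60	diGly	0.92	55	0.006	FALSE	1.8	2.6
U07	K	70	diGly	0.88	45	0.007	FALSE	2.9	0.3
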