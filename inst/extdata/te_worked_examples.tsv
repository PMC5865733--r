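group	model	stage	ct_rpkm	fp_rpkm	ref_te
storage_protein	Glyma.02G012600.1	C300	377	498	1.32
storage_protein	Glyma.10G246300.1	C300	1311	1143	0.87
protein_mobilization	Glyma.08G341500.1	C300	528.44	850.64	1.61
protein_mobilization	Glyma.02G213000.1	C100	0.1	0.1	1.00
ribosomal_protein	Glyma.14G213500.1	C25	87.1	3.6	0.04
ribosomal_protein	Glyma.14G213500.1	C100	56.3	1.5	0.03
ribosomal_protein	Glyma.14G213500.1	C300	180	6.9	0.04
chloroplast_cds	rbcL	C25	1411	74	0.05
chloroplast_cds	psbD_D2	C25	180	22	0.12
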