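transcript_id	protein	ct_utr5	ct_cds	ct_utr3	fp_utr5	fp_cds	fp_utr3	ref_utr5_ratio	ref_cds_ratio	ref_utr3_ratio
Glyma.02G012600.1	lectin	977	19716	1593	36	10842	22	0.07	1.00	0.03
Glyma.01G095000.1	kunitz_trypsin_inhibitor	449	13717	2818	37	7997	64	0.14	1.00	0.04
Glyma.08G341000.1	kunitz_trypsin_inhibitor	43	838	139	0	445	4	0.00	1.00	0.05
Glyma.08G341500.1	kunitz_trypsin_inhibitor	2159	35460	2559	114	26440	78	0.07	1.00	0.04
Glyma.20G148200.1	conglycinin	1564	55629	4953	143	26172	79	0.19	1.00	0.03
Glyma.20G148300.1	conglycinin	4495	101409	5075	328	40697	115	0.18	1.00	0.06
Glyma.20G148400.1	conglycinin	4453	101409	6464	328	40697	140	0.18	1.00	0.05
Glyma.19G164900.1	glycinin	599	22484	1286	10	10100	23	0.04	1.00	0.04
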