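stage	high_te_transcripts	high_te_primary	low_te_transcripts	low_te_primary	expressed_transcripts	expressed_genes
C25	179	136	367	302	26317	14888
C100	90	72	237	218	12503	7683
C300	53	46	265	244	13233	8027
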