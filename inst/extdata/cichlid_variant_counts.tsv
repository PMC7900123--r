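# Published variant-call summary counts for the Tropheus moorii (TM) /
# Petrochromis trewavasae (PT) two-cichlid comparison. Between-species rows
# (PT_vs_TM, TM_vs_PT) map reads of one species against the other's genome;
# within-species rows map reads against the own genome. Lengths in bp.
comparison	metric	value
PT_vs_TM	n_processed	4105604
PT_vs_TM	n_multiallelic	17885
PT_vs_TM	n_effects	9046617
PT_vs_TM	genome_total_length	911126605
PT_vs_TM	effective_length	906396323
PT_vs_TM	snp	3081328
PT_vs_TM	ins	511111
PT_vs_TM	del	513165
PT_vs_TM	sv_duplication	3559
PT_vs_TM	sv_deletion	56396
PT_vs_TM	sv_inversion	1853
PT_vs_TM	sv_translocation	18829
PT_vs_TM	sv_insertion	13205
TM_vs_PT	n_processed	4178777
TM_vs_PT	n_multiallelic	26099
TM_vs_PT	n_effects	8610805
TM_vs_PT	genome_total_length	917573940
TM_vs_PT	effective_length	913305292
TM_vs_PT	snp	3159251
TM_vs_PT	ins	487934
TM_vs_PT	del	531592
TM_vs_PT	sv_duplication	2247
TM_vs_PT	sv_deletion	58692
TM_vs_PT	sv_inversion	1218
TM_vs_PT	sv_translocation	12351
TM_vs_PT	sv_insertion	14981
PT_vs_PT	n_processed	356428
PT_vs_PT	n_multiallelic	2607
PT_vs_PT	n_effects	742872
PT_vs_PT	genome_total_length	917573940
PT_vs_PT	effective_length	905543956
PT_vs_PT	snp	241245
PT_vs_PT	ins	54489
PT_vs_PT	del	60694
PT_vs_PT	sv_duplication	2870
PT_vs_PT	sv_deletion	11989
PT_vs_PT	sv_inversion	1343
PT_vs_PT	sv_translocation	11566
PT_vs_PT	sv_insertion	1316
TM_vs_TM	n_processed	577124
TM_vs_TM	n_multiallelic	3940
TM_vs_TM	n_effects	1305064
TM_vs_TM	genome_total_length	911126605
TM_vs_TM	effective_length	901211269
TM_vs_TM	snp	416002
TM_vs_TM	ins	75775
TM_vs_TM	del	85347
TM_vs_TM	sv_duplication	3628
TM_vs_TM	sv_deletion	21047
TM_vs_TM	sv_inversion	1692
TM_vs_TM	sv_translocation	15022
TM_vs_TM	sv_insertion	2147
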