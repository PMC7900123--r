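# Published variant-effect annotation counts for the TM/PT two-cichlid
# comparison: impact categories over all annotated effects and consequence
# classes over coding-sequence SNP effects.
comparison	group	class	count
PT_vs_TM	impact	HIGH	13761
PT_vs_TM	impact	MODERATE	84185
PT_vs_TM	impact	LOW	149561
PT_vs_TM	impact	MODIFIER	8799110
PT_vs_TM	coding	NONSENSE	788
PT_vs_TM	coding	MISSENSE	78503
PT_vs_TM	coding	SILENT	101260
TM_vs_PT	impact	HIGH	12131
TM_vs_PT	impact	MODERATE	82142
TM_vs_PT	impact	LOW	142956
TM_vs_PT	impact	MODIFIER	8373576
TM_vs_PT	coding	NONSENSE	791
TM_vs_PT	coding	MISSENSE	76737
TM_vs_PT	coding	SILENT	99477
PT_vs_PT	impact	HIGH	2348
PT_vs_PT	impact	MODERATE	7579
PT_vs_PT	impact	LOW	11728
PT_vs_PT	impact	MODIFIER	721217
PT_vs_PT	coding	NONSENSE	77
PT_vs_PT	coding	MISSENSE	6708
PT_vs_PT	coding	SILENT	8010
TM_vs_TM	impact	HIGH	3679
TM_vs_TM	impact	MODERATE	11802
TM_vs_TM	impact	LOW	19951
TM_vs_TM	impact	MODIFIER	1269632
TM_vs_TM	coding	NONSENSE	132
TM_vs_TM	coding	MISSENSE	10871
TM_vs_TM	coding	SILENT	13378
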