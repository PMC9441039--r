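target_id	sample_id	group	ct_target	ct_reference
CCND1	CC_1	CC	25.10	18.02
CCND1	CC_2	CC	25.40	18.31
CCND1	CC_3	CC	24.95	17.88
CCND1	GC_1	GC	23.05	18.10
CCND1	GC_2	GC	23.42	18.26
CCND1	GC_3	GC	23.18	17.95
ITGA6	CC_1	CC	27.80	18.02
ITGA6	CC_2	CC	28.05	18.31
ITGA6	CC_3	CC	27.66	17.88
ITGA6	GC_1	GC	29.10	18.10
ITGA6	GC_2	GC	29.35	18.26
ITGA6	GC_3	GC	28.95	17.95
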