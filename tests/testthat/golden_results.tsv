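# qtlsea_version=0.1.0
# N=300 V=68 mode=any form=within_set alpha=0.05 normalize_scores=FALSE
size	NGQ	NQHits	V	N	SDGQ	E_SDGQ	V_SDGQ	Z	p_value	adj_p	fdr
40	18	20	68	300	-107.205	-444.538	12415.5	3.02744	0.00123316	0.00123316	0.00123316
80	32	36	68	300	-168.243	-563.72	12388.6	3.55311	0.000190349	0.000487851	0.000365888
120	39	43	68	300	-229.634	-612.959	12082.2	3.48734	0.000243926	0.000487851	0.000365888
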