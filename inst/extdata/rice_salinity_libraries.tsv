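# Rice (Oryza sativa, Japonica) salinity-stress RNA-seq study: 24 single-end
# Illumina HiSeq 2000 libraries (read length 50 bp), leaf and root tissue of
# the Vialone Nano and Baldo genotypes, salinity-treated (class_label 1) vs
# control (class_label 0). total_reads is the raw library size.
sample_id	sra_id	genotype	tissue	class_label	total_reads	gc_percent
GSM2940029	SRR6502085	Vialone Nano	Leaves	1	24449975	53
GSM2940030	SRR6502086	Vialone Nano	Leaves	1	20017598	53
GSM2940031	SRR6502087	Vialone Nano	Leaves	1	20827821	52
GSM2940032	SRR6502088	Vialone Nano	Leaves	0	21716861	53
GSM2940033	SRR6502089	Vialone Nano	Leaves	0	20733565	53
GSM2940034	SRR6502090	Vialone Nano	Leaves	0	21422404	54
GSM2940035	SRR6502091	Vialone Nano	Roots	1	27840276	52
GSM2940036	SRR6502092	Vialone Nano	Roots	1	23879836	53
GSM2940037	SRR6502093	Vialone Nano	Roots	1	19205417	51
GSM2940038	SRR6502094	Vialone Nano	Roots	0	19717555	54
GSM2940039	SRR6502095	Vialone Nano	Roots	0	19368950	54
GSM2940040	SRR6502096	Vialone Nano	Roots	0	21735612	53
GSM2940041	SRR6502097	Baldo	Leaves	1	21831739	53
GSM2940042	SRR6502098	Baldo	Leaves	1	19588041	52
GSM2940043	SRR6502099	Baldo	Leaves	1	18806965	53
GSM2940044	SRR6502100	Baldo	Leaves	0	23497719	54
GSM2940045	SRR6502101	Baldo	Leaves	0	20177524	55
GSM2940046	SRR6502102	Baldo	Leaves	0	18961877	54
GSM2940047	SRR6502103	Baldo	Roots	1	19608758	51
GSM2940048	SRR6502104	Baldo	Roots	1	24485505	51
GSM2940049	SRR6502105	Baldo	Roots	1	34395309	54
GSM2940050	SRR6502106	Baldo	Roots	0	24854382	53
GSM2940051	SRR6502107	Baldo	Roots	0	30769580	52
GSM2940052	SRR6502108	Baldo	Roots	0	24416471	51
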