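# Rice stress gene expression datasets: retained gene counts and sample
# splits per stress. For the drought microarray meta-dataset the preliminary
# gene-selection arithmetic is recorded: n_genes_initial genes before
# filtering, of which n_control_removed control probe sets and
# n_irrelevant_removed irrelevant genes were removed (fold-change and
# t-test p-value thresholds of 1 and 0.05). NA where not recorded.
dataset	platform	n_series	n_genes	n_case	n_control	n_genes_initial	n_control_removed	n_irrelevant_removed
salinity	RNA-seq	1	26454	12	12	NA	NA	NA
cold	microarray	4	8840	15	13	NA	NA	NA
drought	microarray	5	9078	35	35	57381	123	48180
fungal	microarray	2	7072	13	13	NA	NA	NA
insect	microarray	1	7241	12	6	NA	NA	NA
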