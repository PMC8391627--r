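qtl_id	trait	chrom	start	stop
q001	synthetic	chr1	332963	384708
q002	synthetic	chr3	421460	468606
q003	synthetic	chr1	37001	85025
q004	synthetic	chr3	381847	448223
q005	synthetic	chr3	81459	148169
q006	synthetic	chr1	90810	145164
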