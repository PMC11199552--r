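individual_id	phenotype_id	status
f01_1	trait	1
f01_3	trait	1
f02_2	trait	1
f03_4	trait	1
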