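species	value
HIF1AB	0
HIF2AB_HRE1	0
HIF1AB_HRE1	0
Gene_mRNA	1
HIF2AB_HRE2	0
HIF1AB_HRE2	0
HIF2AB	0
HIF1B	60
PHD_protein	1
HIF1A_mrna	1
HIF2A_mrna	1
HIF1A_protein	1
HIF2A_protein	5.26
HIF2A_protein_total	1
HIF1A_protein_total	1
O2	1
HRE1	12
HRE2	18
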