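protein	condition	time_h	absolute_ng_per_mg
HIF1A	normoxia	0	0.196
HIF1A	hypoxia_2h	2	0.546
HIF1A	hypoxia_8h	8	0.660
HIF2A	normoxia	0	0.068
HIF2A	hypoxia_8h	8	3.468
HIF2A	hypoxia_24h	24	2.868
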