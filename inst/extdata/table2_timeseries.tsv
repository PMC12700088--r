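time (hours)	HIF1A protein	HIF2A protein	HIF2A protein scaled	PHD protein	HIF1A mRNA	HIF2A mRNA	MIR210HG mRNA
0	1.0000	1.0000	5.2606	1.0000	1.0000	1.0000	1.0000
2	4.6080	1.9469	10.2416	1.2631	0.5800	0.6475	6.8630
4	6.2155	2.3412	12.3161	1.3703	0.6100	0.7841
6	8.4539	5.1084	26.8728	1.8831	0.4000	0.7462
8	7.6271	5.5638	29.2685	2.1122	0.2600	0.5248	40.6453
10	5.8307	6.7598	35.5602	2.6777	0.2500	0.8267
12	4.7802	6.5332	34.3684	2.5870	0.2500	0.5701
16	3.0066	6.5175	34.2855	3.6042	0.1300	0.5221	46.2323
20	3.0746	5.5817	29.3627	3.5460	0.2600	0.7198
24	2.1006	4.3697	22.9869	4.3130	0.3600	0.8510
36	2.4858	4.7546	25.0117	5.7481	0.4100	0.8653
48	1.3927	3.5150	18.4910	6.2099	1.0500	1.8974
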