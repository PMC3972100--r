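ligand_id	logp	hsa_percent	2BXP:site_I	1N5U:site_II
syn0001	2.7515	76.72	-18.298	-15.965
syn0002	4.0816	70.83	-16.04	-15.677
syn0003	3.7879	80.68	-16.146	-15.323
syn0004	5.6298	100	-16.073	-14.951
syn0005	1.6684	88.72	-23.86	-23.151
syn0006	4.0838	94.96	-16.178	-15.706
syn0007	4.0004	82.8	-10.693	-14.602
syn0008	4.1996	62.43	-14.977	-14.499
syn0009	4.2883	85.68	-14.274	-16.79
syn0010	4.0141	98.88	-19.043	-19.169
syn0011	5.2293	100	-16.204	-14.416
syn0012	3.6553	91.21	-12.008	-15.258
syn0013	4.1819	95.73	-16.573	-16.082
syn0014	3.3834	81.5	-15.31	-19.393
syn0015	2.5188	93.65	-20.111	-23.023
syn0016	4.9789	100	-11.034	-13.527
syn0017	3.3519	100	-19.605	-23.432
syn0018	6.3576	90.62	-6.506	-10.111
syn0019	3.8109	100	-15.105	-17.632
syn0020	4.5965	95.19	-9.829	-17.454
syn0021	3.7611	81.78	-16.326	-15.223
syn0022	5.218	85.4	-12.535	-12.134
syn0023	5.7451	79.18	-14.209	-13.263
syn0024	3.1386	82.8	-15.655	-16.19
syn0025	3.7185	100	-16.662	-18.176
syn0026	7.33	94.21	-4.929	-5.263
syn0027	6.7117	84.68	-7.112	-5.626
syn0028	4.0967	92.3	-12.993	-16.469
syn0029	1.7209	65.25	-23.037	-22.064
syn0030	5.6045	99.71	-8.152	-12
syn0031	-2.9105	21.78	-8.27	-7.668
syn0032	-0.5633	23.47	-6.822	-6.372
syn0033	-0.4661	32.89	-1.156	-0.879
syn0034	2.9998	17.21	15.221	15.605
syn0035	-2.2633	17.79	-6.261	-4.959
syn0036	-2.155	13.8	-2.112	-2.291
syn0037	1.4946	27.24	6.632	5.728
syn0038	-2.7123	26.11	-7.093	-6.785
syn0039	-3.3115	33.21	-15.731	-15.696
syn0040	-0.5867	11.88	1.814	0.853
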