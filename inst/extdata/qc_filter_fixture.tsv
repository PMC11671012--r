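protein_id	rate_per_day	rsq	n_unique_peptides	asymptote	deviation
FIX001	1.3765	0.2786	1	1	0.0503
FIX002	1.4088	0.4136	1	1	0.0152
FIX003	0.4649	0.3967	1	1	0.0215
FIX004	1.2541	0.2833	1	1	0.0618
FIX005	0.9805	0.2381	1	1	0.0433
FIX006	0.8027	0.2148	3	1	0.058
FIX007	1.1181	0.4027	5	1	0.0766
FIX008	0.2453	0.5025	3	1	0.0448
FIX009	1.0026	0.4806	4	1	0.0429
FIX010	1.0723	0.2768	3	1	0.0492
FIX011	0.7137	0.8961	1	1	0.0557
FIX012	1.0927	0.9508	1	1	0.0296
FIX013	1.4053	0.9304	1	1	0.0786
FIX014	0.4204	0.8587	1	1	0.0551
FIX015	0.7203	0.8786	1	1	0.0508
FIX016	0	0.879	2	1	0.0531
FIX017	0	0.7503	6	1	0.0748
FIX018	0	0.8354	4	1	0.0373
FIX019	0	0.8969	5	1	0.0302
FIX020	0	0.9489	3	1	0.0164
FIX021	1.3608	0.8356	2	1	0.0325
FIX022	0.2511	0.8486	6	1	0.0631
FIX023	1.4839	0.8876	4	1	0.0173
FIX024	1.4227	0.8915	3	1	0.0597
FIX025	0.1695	0.9227	6	1	0.0777
FIX026	0.7956	0.8448	4	1	0.0241
FIX027	0.6158	0.9706	5	1	0.0176
FIX028	1.3633	0.981	3	1	0.0139
FIX029	0.6981	0.806	2	1	0.0681
FIX030	1.2622	0.9239	4	1	0.0507
FIX031	1.1195	0.9669	4	1	0.0429
FIX032	1.226	0.8948	5	1	0.0356
FIX033	0.6128	0.9016	5	1	0.0296
FIX034	1.0435	0.975	5	1	0.052
FIX035	0.0557	0.9541	4	1	0.0673
FIX036	1.2577	0.8892	2	1	0.0168
FIX037	0.0606	0.9471	2	1	0.0775
FIX038	0.3511	0.7773	2	1	0.0218
FIX039	1.3646	0.9335	6	1	0.016
FIX040	0.9371	0.8997	5	1	0.0703
FIX041	0.6004	0.7856	2	1	0.0467
FIX042	0.6819	0.7693	6	1	0.056
FIX043	0.1043	0.8614	5	1	0.0261
FIX044	1.4616	0.937	2	1	0.0605
FIX045	0.676	0.926	2	1	0.0444
FIX046	1.4385	0.9461	2	1	0.0776
FIX047	1.3372	0.7908	5	1	0.0735
FIX048	0.978	0.9767	3	1	0.0486
FIX049	1.4579	0.8205	4	1	0.0153
FIX050	0.9473	0.7858	6	1	0.0116
FIX051	0.5335	0.9227	6	1	0.0459
FIX052	0.5528	0.8278	5	1	0.0542
FIX053	0.6278	0.9369	2	1	0.0393
FIX054	1.1878	0.8447	4	1	0.0715
FIX055	0.1065	0.9129	5	1	0.0176
FIX056	1.1358	0.9362	6	1	0.0786
FIX057	1.0321	0.7951	3	1	0.0285
FIX058	0.2983	0.757	2	1	0.0159
FIX059	0.4286	0.7826	2	1	0.037
FIX060	0.7959	0.9132	2	1	0.0187
FIX061	1.0296	0.9744	4	1	0.0507
FIX062	1.4751	0.8821	3	1	0.0268
FIX063	1.1513	0.8944	6	1	0.0605
FIX064	0.8714	0.7973	5	1	0.0202
FIX065	1.2821	0.8785	5	1	0.0207
FIX066	0.3247	0.7931	6	1	0.0281
FIX067	0.4434	0.8585	2	1	0.0645
FIX068	1.2508	0.8261	5	1	0.0399
FIX069	1.0551	0.7779	2	1	0.0142
FIX070	0.3988	0.7947	2	1	0.018
FIX071	0.1123	0.9251	6	1	0.0438
FIX072	0.2537	0.8488	4	1	0.0785
FIX073	0.3638	0.8494	2	1	0.0668
FIX074	0.7451	0.8653	3	1	0.048
FIX075	0.3362	0.8526	5	1	0.0151
FIX076	1.0931	0.7828	3	1	0.0427
FIX077	0.0614	0.9479	6	1	0.0338
FIX078	0.5945	0.8922	6	1	0.0583
FIX079	0.7959	0.9407	4	1	0.046
FIX080	0.0523	0.9346	6	1	0.046
FIX081	0.8933	0.9703	3	1	0.0482
FIX082	0.279	0.957	2	1	0.0413
FIX083	0.5706	0.8261	2	1	0.0159
FIX084	0.9862	0.8122	2	1	0.0751
FIX085	1.1749	0.9281	4	1	0.0112
FIX086	0.8673	0.9294	5	1	0.039
FIX087	0.3889	0.9703	3	1	0.0259
FIX088	0.1805	0.9404	3	1	0.017
FIX089	0.1741	0.782	3	1	0.0438
FIX090	0.4926	0.8191	3	1	0.0555
FIX091	1.0178	0.7967	5	1	0.0745
FIX092	0.0503	0.9382	5	1	0.0354
FIX093	0.3524	0.7809	6	1	0.0699
FIX094	1.4029	0.781	2	1	0.0311
FIX095	1.3922	0.7673	4	1	0.0426
FIX096	1.1144	0.7628	6	1	0.02
FIX097	0.533	0.8776	5	1	0.0665
FIX098	0.7968	0.777	3	1	0.0566
FIX099	1.1288	0.9284	3	1	0.0143
FIX100	0.9478	0.9255	2	1	0.0402
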