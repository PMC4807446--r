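specimen	avg_reads_per_timp	pct_timps	rank_pct_timps	pct_timp_reads	rank_pct_timp_reads
Asteropsis carinifera	915.2	0.012	33	0.018	21
Astropecten duplicatus	183.9	0.015	29	0.007	27
Cheiraster hirsutus	NA	0.000	39.5	0.000	39.5
Henricia cf. leviuscula	739.0	0.013	30	0.025	16
Labidiaster annulatus	1339.3	0.022	24	0.011	26
Luidia clathrata	983.6	0.006	37	0.017	22
Odinella nutrix	NA	0.000	39.5	0.000	39.5
Peribolaster folliculatus	163.9	0.026	19	0.004	32
Pisaster ochraceus	1514.6	0.030	15	0.014	23
Glabraster antarctica	100.9	0.013	31	0.003	33
Psilaster charcoti	1167.2	0.032	13	0.022	17
Pteraster tesselatus	10672.2	0.025	21	0.097	8
Remaster gourdoni	363.8	0.023	23	0.005	30
Xyloplax janetae	119.7	0.012	32	0.002	34
Cenolia n. sp.	1417.0	0.026	18	0.051	13
Democrinus brevis	4428.2	0.072	8	0.112	7
Gephyrocrinus messingi	1405.5	0.016	27	0.012	25
Isometra vivipara	1523.0	0.021	26	0.048	14
Oligometra serripinna	4501.6	0.028	16	0.058	11
Phrixometra nutrix	2134.7	0.025	20	0.046	15
Promachocrinus kerguelensis	2472.2	0.049	12	0.143	6
Psathryometra fragilis	NA	0.000	39.5	0.000	39.5
Ptilometra australis	3037.5	0.028	17	0.157	4
Arbacia punctulata	380.7	0.009	36	0.007	28
Dendraster excentricus	55.7	0.024	22	0.001	35
Echinaster spinulosus	15.5	0.011	35	0.000	37
Eucidaris tribuloides	122.0	0.030	14	0.005	29
Strongylocentrotus purpuratus	296.4	0.062	10	0.018	20
Abyssocucumis sp.	682.0	0.122	3	0.162	3
Molpadia intermedia	317.4	0.107	5	0.012	24
Peniagone sp.	1351.5	0.107	6	0.151	5
Pannychia moseleyi	1296.5	0.065	9	0.088	9
Pseudostichopus sp.	180.0	0.054	11	0.005	31
Psolus sp. 11	772.2	0.127	2	0.082	10
Psolus sp. 41	324.4	0.136	1	0.054	12
Stichopus chloronotus	14891.8	0.080	7	0.546	2
Synapta maculata	41227.4	0.117	4	1.124	1
Astrophyton muricatum	1210.0	0.011	34	0.020	19
Ophiocoma wendtii	NA	0.000	39.5	0.000	39.5
Ophioderma brevispinum	589.2	0.021	25	0.020	18
Ophiothrix spiculata	26.3	0.016	28	0.000	36
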