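specimen	clade	contigs	reads	timp_contigs	timp_reads
Asteropsis carinifera	Asteroidea	49607	30392805	6	5491
Astropecten duplicatus	Asteroidea	73745	29277239	11	2023
Cheiraster hirsutus	Asteroidea	1271	2159361	0	0
Henricia cf. leviuscula	Asteroidea	76684	29546206	10	7390
Labidiaster annulatus	Asteroidea	40071	112755029	9	12054
Luidia clathrata	Asteroidea	77487	28501794	5	4918
Odinella nutrix	Asteroidea	1004	4134835	0	0
Peribolaster folliculatus	Asteroidea	57013	69119595	15	2459
Pisaster ochraceus	Asteroidea	43479	139502413	13	19690
Glabraster antarctica	Asteroidea	54328	21039565	7	706
Psilaster charcoti	Asteroidea	28413	46739511	9	10505
Pteraster tesselatus	Asteroidea	51764	142489961	13	138738
Remaster gourdoni	Asteroidea	22056	36388063	5	1819
Xyloplax janetae	Asteroidea	24452	20903794	3	359
Cenolia n. sp.	Crinoidea	18875	13882168	5	7085
Democrinus brevis	Crinoidea	8287	23656961	6	26569
Gephyrocrinus messingi	Crinoidea	12234	24258898	2	2811
Isometra vivipara	Crinoidea	43689	28460271	9	13707
Oligometra serripinna	Crinoidea	70278	156085944	20	90031
Phrixometra nutrix	Crinoidea	11855	13923251	3	6404
Promachocrinus kerguelensis	Crinoidea	12283	10362958	6	14833
Psathryometra fragilis	Crinoidea	9015	27444619	0	0
Ptilometra australis	Crinoidea	49470	27016836	14	42525
Arbacia punctulata	Echinoidea	33220	16672722	3	1142
Dendraster excentricus	Echinoidea	12561	13766000	3	167
Echinaster spinulosus	Echinoidea	18608	31429052	2	31
Eucidaris tribuloides	Echinoidea	16512	11565762	5	610
Strongylocentrotus purpuratus	Echinoidea	11368	11237474	7	2075
Abyssocucumis sp.	Holothuroidea	26171	13434829	32	21824
Molpadia intermedia	Holothuroidea	6516	18146083	7	2222
Peniagone sp.	Holothuroidea	22457	21508002	24	32436
Pannychia moseleyi	Holothuroidea	20051	19231829	13	16855
Pseudostichopus sp.	Holothuroidea	5567	10992832	3	540
Psolus sp. 11	Holothuroidea	35310	42192822	45	34748
Psolus sp. 41	Holothuroidea	33062	27131787	45	14600
Stichopus chloronotus	Holothuroidea	24854	54588991	20	297835
Synapta maculata	Holothuroidea	11154	47675387	13	535956
Astrophyton muricatum	Ophiuroidea	26889	17829133	3	3630
Ophiocoma wendtii	Ophiuroidea	9783	5810700	0	0
Ophioderma brevispinum	Ophiuroidea	28450	17347877	6	3535
Ophiothrix spiculata	Ophiuroidea	18816	20275162	3	79
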