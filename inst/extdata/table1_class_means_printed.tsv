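clade	n	contigs	reads	timp_contigs	timp_reads	avg_reads_per_timp	pct_timps	rank_pct_timps	pct_timp_reads	rank_pct_timp_reads
Asteroidea	14	42955	50925012	7.6	14725	1521.9	0.016	27.6	0.016	26.3
Crinoidea	9	26221	36121323	7.2	22663	2614.9	0.030	20.4	0.070	14.9
Echinoidea	5	18454	16934202	4.0	805	174.1	0.027	23.4	0.006	29.8
Holothuroidea	9	20571	28322507	22.4	106335	6782.6	0.102	5.3	0.247	10.8
Ophiuroidea	4	20985	15315718	3.0	1811	608.5	0.012	31.6	0.010	28.1
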