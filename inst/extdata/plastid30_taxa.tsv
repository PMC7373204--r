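taxon	lineage	classification	accession	n_genes	pct_missing	pct_gc
Chlorella_vulgaris	Chlorophyta	Trebouxiophyceae	NC_001865	65	21.28	38.24
Chlamydomonas_reinhardtii	Chlorophyta	Chlorophyceae	NC_005353	57	32.39	36.30
Ostreococcus_tauri	Chlorophyta	prasinophytes	NC_008289	54	35.56	42.02
Nephroselmis_olivacea	Chlorophyta	prasinophytes	NC_000927	74	4.81	43.13
Mesostigma_viride	Streptophyta	Mesostigmales	NC_002186	79	3.55	33.57
Chlorokybus_atmophyticus	Streptophyta	Chlorokybales	NC_008822	81	1.66	37.96
Klebsormidium_flaccidum	Streptophyta	Klebsormidiales	NC_024167	73	7.23	43.33
Chara_vulgaris	Streptophyta	Charales	NC_008097	81	1.34	34.63
Chaetosphaeridium_globosum	Streptophyta	Coleochaetales	NC_004115	83	0.09	33.77
Staurastrum_punctulatum	Streptophyta	Desmidiales	NC_008116	81	1.22	35.77
Zygnema_circumcarinatum	Streptophyta	Zygnematales	NC_008117	81	0.90	37.93
Mesotaenium_endlicherianum	Streptophyta	Zygnematales	NC_024169	81	0.74	44.29
Roya_anglica	Streptophyta	Zygnematales	NC_024168	81	0.47	36.63
Pellia_endiviifolia	Streptophyta	Marchantiophyta	NC_019628	82	0.50	38.24
Ptilidium_pulcherrimum	Streptophyta	Marchantiophyta	NC_015402	77	10.70	35.72
Physcomitrella_patens	Streptophyta	Bryophyta	NC_005087	80	2.84	33.46
Syntrichia_ruralis	Streptophyta	Bryophyta	NC_012052	77	9.90	33.21
Nothoceros_aenigmaticus	Streptophyta	Anthocerotophyta	NC_020259	81	2.80	39.10
Anthoceros_formosae	Streptophyta	Anthocerotophyta	NC_004543	81	1.92	37.31
Isoetes_flaccida	Streptophyta	Lycopodiophyta	NC_014675	79	3.83	40.75
Huperzia_lucidula	Streptophyta	Lycopodiophyta	NC_006861	83	0.03	38.98
Selaginella_moellendorffii	Streptophyta	Lycopodiophyta	NC_013086	66	10.12	50.77
Equisetum_hyemale	Streptophyta	Moniliformopses	NC_020146	81	0.52	36.02
Psilotum_nudum	Streptophyta	Moniliformopses	KC117179	79	7.68	38.57
Angiopteris_evecta	Streptophyta	Moniliformopses	NC_008829	83	0.01	38.01
Adiantum_capillus-veneris	Streptophyta	Moniliformopses	NC_004766	79	7.31	43.42
Pinus_thunbergii	Streptophyta	Spermatophyta	NC_001631	69	20.61	40.65
Cycas_revoluta	Streptophyta	Spermatophyta	JN867588	81	1.08	40.72
Arabidopsis_thaliana	Streptophyta	Spermatophyta	NC_000932	76	8.70	39.04
Nymphaea_alba	Streptophyta	Spermatophyta	NC_006050	77	8.20	41.01
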