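# Transcription of the published 15-anomaly accounting for the 20 Thermococcaceae
# GtRNAdb gene sets (12 gene records; paired additional/missing anomalies share a row).
# direction columns: the predicted ("additional") type, and the standard type it
# displaces ("missing") where one exists. Coordinates are 1-based inclusive.
# category: 1a = CRISPR-derived fragment, 1b = integration (attR) fragment,
# 2 = isotype misassignment from ambiguous (N) bases, 3 = legitimate duplicate.
anomaly_ids	isotype	anticodon	missing_isotype	missing_anticodon	size_bp	isotype_score	isotype_score_local	organism	genome_id	start	end	strand	trnascan_class	gtrnadb_class	category
1	Ser	CGA	NA	NA	53	10.4	NA	Thermococcus gammatolerans EJ3	Tgammatolerans_EJ3	621672	621724	-	Ps	St	1b
2	Leu	CAA	NA	NA	218	2.3	NA	Thermococcus nautili 30-1	Tnautili_30-1	706451	706668	+	Ps	St	1a
3	Arg	TCT	NA	NA	83	21.4	NA	Thermococcus kodakarensis KOD1	Tkodakarensis_KOD1	320075	320157	-	Ps	St	1b
4	Val	CAC	NA	NA	72	83.4	NA	Thermococcus kodakarensis KOD1	Tkodakarensis_KOD1	62858	62929	-	St	St	1b
5	Gln	TTG	NA	NA	90	13.4	NA	Pyrococcus yayanosii CH1	Pyayanosii_CH1	1321660	1321749	-	Ps	St	1b
6	Ser	CGA	NA	NA	69	30.9	NA	Thermococcus sp. ES1	Tsp_ES1	747982	748050	+	Ps	St	1b
7	Und	NNN	NA	NA	127	16.8	NA	Thermococcus sp. ES1	Tsp_ES1	603860	603986	-	Und	Und	1b
8	Leu	CAA	NA	NA	76	6.3	NA	Thermococcus litoralis DSM 5473	Tlitoralis_DSM5473	326949	327024	+	Ps	St	1b
9,10	Leu	NAG	Leu	CAG	88	135.1	134.9	Thermococcus litoralis DSM 5473	Tlitoralis_DSM5473	648439	648526	+	Ps	St	2
11,12	Pro	NGG	Pro	GGG	78	120.3	120.3	Thermococcus litoralis DSM 5473	Tlitoralis_DSM5473	546230	546307	-	Ps	St	2
13,14	Und	NTG	Gln	CTG	76	117.9	117.9	Thermococcus litoralis DSM 5473	Tlitoralis_DSM5473	825204	825279	-	Ps	St	2
15	Ala	TGC	NA	NA	77	122.6	NA	Palaeococcus pacificus DY20341	Ppacificus_DY20341	1527238	1527314	-	St	St	3
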