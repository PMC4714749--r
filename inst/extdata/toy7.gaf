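!gaf-version: 2.2
DB	g1	g1	involved_in	GO:0100007	REF:1	IDA	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g2	g2	involved_in	GO:0100004	REF:1	IMP	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g3	g3	involved_in	GO:0100005	REF:1	IEA	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g4	g4	involved_in	GO:0100006	REF:1	TAS	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g5	g5	involved_in	GO:0100002	REF:1	IGI	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g6	g6	NOT	GO:0100003	REF:1	IDA	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g6	g6	involved_in	GO:0100003	REF:1	IPI	-	F	-	-	protein	taxon:0	20200101	DB	-	-
DB	g7	g7	involved_in	GO:0100007	REF:1	IEP	-	F	-	-	protein	taxon:0	20200101	DB	-	-
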