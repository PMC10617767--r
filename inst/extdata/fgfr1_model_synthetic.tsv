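gene	element_type	name	start	end	frame_or_aa
FGFR1	gene	FGFR1	38268756	38326352	-
FGFR1	tss	tss	38326352	38326352	-
FGFR1	exon	exon1	38326053	38326352	1
FGFR1	exon	exon2	38322625	38322844	2
FGFR1	exon	exon3	38319237	38319416	3
FGFR1	exon	exon4	38315924	38316028	4
FGFR1	exon	exon5	38312581	38312715	5
FGFR1	exon	exon6	38309163	38309372	6
FGFR1	exon	exon7	38305775	38305954	7
FGFR1	exon	exon8	38302432	38302566	8
FGFR1	exon	exon9	38299029	38299223	9
FGFR1	exon	exon10	38295671	38295820	10
FGFR1	exon	exon11	38292329	38292463	11
FGFR1	exon	exon12	38288978	38289121	12
FGFR1	exon	exon13	38285639	38285770	13
FGFR1	exon	exon14	38282291	38282431	14
FGFR1	exon	exon15	38278946	38279083	15
FGFR1	exon	exon16	38275604	38275738	16
FGFR1	exon	exon17	38272262	38272396	17
FGFR1	exon	exon18	38268756	38269054	18
FGFR1	cds	start_codon	38322742	38322744	0
FGFR1	cds	stop_codon	38268956	38268958	0
FGFR1	domain	IG-I	25	119	aa
FGFR1	domain	acid box	126	138	aa
FGFR1	domain	IG-II	158	246	aa
FGFR1	domain	IG-III	255	357	aa
FGFR1	domain	TM	377	397	aa
FGFR1	domain	kinase	478	767	aa
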