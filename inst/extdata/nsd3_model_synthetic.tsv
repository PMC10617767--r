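gene	element_type	name	start	end	frame_or_aa
NSD3	gene	NSD3	38132544	38239790	+
NSD3	tss	tss	38132544	38132544	+
NSD3	exon	exon1	38132544	38132858	1
NSD3	exon	exon2	38137315	38137488	2
NSD3	exon	exon3	38141945	38142124	3
NSD3	exon	exon4	38146581	38146766	4
NSD3	exon	exon5	38151223	38151387	5
NSD3	exon	exon6	38155844	38156023	6
NSD3	exon	exon7	38160480	38160653	7
NSD3	exon	exon8	38165110	38165295	8
NSD3	exon	exon9	38169752	38169931	9
NSD3	exon	exon10	38174388	38174573	10
NSD3	exon	exon11	38179030	38179203	11
NSD3	exon	exon12	38183660	38183839	12
NSD3	exon	exon13	38188296	38188481	13
NSD3	exon	exon14	38192938	38193117	14
NSD3	exon	exon15	38197574	38197747	15
NSD3	exon	exon16	38202204	38202413	16
NSD3	exon	exon17	38206870	38207094	17
NSD3	exon	exon18	38211551	38211790	18
NSD3	exon	exon19	38216247	38216426	19
NSD3	exon	exon20	38220882	38221046	20
NSD3	exon	exon21	38225502	38225675	21
NSD3	exon	exon22	38230131	38230295	22
NSD3	exon	exon23	38234751	38234900	23
NSD3	exon	exon24	38239356	38239790	24
NSD3	cds	start_codon	38132694	38132696	0
NSD3	cds	stop_codon	38239488	38239490	0
NSD3	domain	PWWP	270	330	aa
NSD3	domain	PHD	580	640	aa
NSD3	domain	SET	1152	1262	aa
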