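sample	chrom1	pos1	side1	chrom2	pos2	side2	support	provenance
TUM004	chr8	38323798	left	chr8	38324448	left	192	published: intragenic TT deleting exon 1 (support 192); synthetic intron-1 coordinates
TUM006	chr8	38316912	left	chr8	38317632	left	115	published: intragenic TT deleting exons 1-3 (support 115); synthetic intron-3 coordinates
TUM009	chr8	38520000	left	chr8	38520650	left	77	synthetic: upstream TT, H1581-like pattern described for TUM009
TUM009	chr8	38197660	left	chr8	41510000	right	40	synthetic: NSD3 exon-15 out-of-frame fusion into ANK1 region
TUM002	chr8	2.1e+07	left	chr8	23500000	right	12	synthetic: background deletion, TT-negative responder
H1581	chr8	38595657	left	chr8	38596262	left	88	published coordinate chr8:38,595,657 (upstream TT); mate/support synthetic
H1581	chr8	38197720	left	chr8	41512345	right	35	published: NSD3 exon 15 fused to ANK1 exon 10; synthetic coordinates
DMS114	chr8	38382689	left	chr8	38383295	left	64	published coordinate chr8:38,382,689 (upstream TT); mate/support synthetic
PDX003	chr8	38371080	left	chr8	38371700	left	58	published coordinate chr8:38,371,080 (upstream TT); mate/support synthetic
PDX003	chr8	38199975	left	chr8	38245000	right	30	published: deletion of NSD3 exons 16-24; synthetic intron-15 coordinates
PDX006	chr8	38167523	left	chr8	38247000	right	28	published: deletion of NSD3 exons 9-24; synthetic intron-8 coordinates
PDX008	chr8	38481135	left	chr8	38481760	left	52	published coordinate chr8:38,481,135 (upstream TT); mate/support synthetic
PDX008	chr8	38167563	left	chr8	38246100	right	33	published: deletion of NSD3 exons 9-24; synthetic intron-8 coordinates
CL001	chr8	38560000	left	chr8	38560620	left	41	synthetic: upstream TT in a nonresponder (3 of 12 unnamed in the source)
TUM003	chr8	38402500	left	chr8	38403080	left	23	synthetic: upstream TT in a nonresponder
PDX004	chr8	38650750	left	chr8	38651300	left	37	synthetic: upstream TT in a nonresponder
PDX001	chr8	38310976	right	chr8	38311576	right	45	published: head-to-head fold-back deleting NSD3 and FGFR1 exons 6-18; synthetic intron-5 coordinates
PDX002	chr8	36200000	right	chr8	36200700	right	21	synthetic: distal fold-back, outside FGFR1 window
PDX007	chr8	30100000	left	chr8	33900000	right	9	synthetic: background deletion
TUM005	chr8	3.7e+07	right	chr8	37000500	right	18	synthetic: distal fold-back below FGFR1
TUM008	chr8	39500000	left	chr8	39501000	left	14	synthetic: TT beyond the 400 kb window (negative control)
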