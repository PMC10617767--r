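gene	chrom	start	end	strand
FGFR1	chr8	38268756	38326352	-
NSD3	chr8	38132544	38239790	+
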