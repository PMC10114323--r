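event	dnm_type	chrom	start	end	parent_of_origin	locus	mechanism	proband_trios	n_offspring_transmission_example
cluster1	DUP	chr1	2940197	2940384	unknown	PDE10A	NON_HOM	37	4
cluster1	SNV	chr1	2940375	2940375	unknown	PDE10A	NA	37	4
cluster1	DEL	chr1	2940383	2940394	unknown	PDE10A	NON_HOM	37	4
cluster2	DEL	chr1	95207720	95210792	paternal	SLC14A2	MICRO_HOM	37	4
cluster2	DUP	chr1	95210182	95213638	paternal	SLC14A2	unresolved	37	4
cluster2	DUP	chr1	95213834	95214842	paternal	SLC14A2	NON_HOM	37	4
cluster2	DUP	chr1	95214800	95232460	paternal	SLC14A2	MICRO_HOM	37	4
single1	DUP	chr7	37837360	37837933	unknown	BICRAL	NON_HOM	37	4
single2	DEL	chr15	18965177	18965241	unknown	NCKAP5	NON_HOM	37	4
mosaic1	DEL	chr11	53586793	53587069	unknown	intergenic	MICRO_HOM	37	4
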