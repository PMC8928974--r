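rs_id	chrom	pos	normal_allele	risk_allele	pvalue
rs0000101	chr1	150500	A	G	2.1e-08
rs0000102	chr1	982400	C	T	5.5e-07
rs0000103	chr2	77150	G	A	3.0e-06
rs0000104	chr2	431800	T	C	8.8e-07
rs0000105	chr3	120950	C	G	1.4e-06
rs0000106	chr3	655210	A	T	9.9e-06
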