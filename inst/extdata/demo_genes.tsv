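chrom	start	end	feature_id	feature_name	feature_class
1	475001	550000	ENSDEMO001	GENE_A1	gene
1	1530001	1600000	ENSDEMO002	GENE_A2	gene
1	2200001	2250000	ENSDEMO003	GENE_A3	gene
1	3005001	3020000	ENSDEMO004	GENE_A4	gene
1	4150001	4300000	ENSDEMO005	GENE_A5	gene
2	450001	505000	ENSDEMO006	GENE_B1	gene
2	700001	755000	ENSDEMO007	GENE_B2	gene
2	2500001	2600000	ENSDEMO008	GENE_B3	gene
2	3525001	3540000	ENSDEMO009	GENE_B4	gene
3	770001	790000	ENSDEMO010	GENE_C1	gene
3	2530001	2580000	ENSDEMO011	GENE_C2	gene
3	4500001	4750000	ENSDEMO012	GENE_C3	gene
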