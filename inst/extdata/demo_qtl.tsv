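chrom	start	end	feature_id	feature_name	feature_class
1	250001	1000000	QTLDEMO01	MilkYieldQTL	qtl
2	3250001	4000000	QTLDEMO02	ConformationQTL	qtl
3	500001	1250000	QTLDEMO03	DailyGainQTL	qtl
3	2400001	2520000	QTLDEMO04	SomaticCellQTL	qtl
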