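id	rna_class	precursor_id	mature_offset	chrom	start	end	strand
hY4-synthetic	YRNA			chr6	51348700	51348794	-
mirna-001	miRNA	pre-mirna-001	10	chr7	65393600	65393620	-
mirna-002	miRNA	pre-mirna-002	10	chr7	69156150	69156170	+
mirna-003	miRNA	pre-mirna-003	10	chr3	43953900	43953920	-
mirna-004	miRNA	pre-mirna-004	10	chr8	23718200	23718221	+
mirna-005	miRNA	pre-mirna-005	10	chr4	94587850	94587870	+
mirna-006	miRNA	pre-mirna-006	10	chr2	74146900	74146922	-
mirna-007	miRNA	pre-mirna-007	10	chr1	9803700	9803722	+
mirna-008	miRNA	pre-mirna-008	10	chr4	8243900	8243923	+
yrna-001	YRNA			chr5	16600900	16600996	+
yrna-002	YRNA			chr2	99119750	99119846	+
yrna-003	YRNA			chr5	26661100	26661196	-
trna-001	tRNA			chr4	41070150	41070223	-
trna-002	tRNA			chr2	6517550	6517623	+
trna-003	tRNA			chr3	95433550	95433623	-
rrna-001	rRNA			chr5	69434750	69434870	+
rrna-002	rRNA			chr6	74049750	74049870	+
snrna-001	snRNA			chr6	40688550	40688656	-
snrna-002	snRNA			chr3	59654100	59654206	-
snorna-001	snoRNA			chr3	96936800	96936880	+
snorna-002	snoRNA			chr8	35228100	35228180	-
pirna-001	piRNA			chr2	9800500	9800526	-
pirna-002	piRNA			chr4	71023700	71023726	+
pirna-003	piRNA			chr8	57281600	57281628	+
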