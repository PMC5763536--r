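chr6	51348700	51348794	hY4-synthetic	0	-
chr7	65393600	65393620	mirna-001	0	-
chr7	69156150	69156170	mirna-002	0	+
chr3	43953900	43953920	mirna-003	0	-
chr8	23718200	23718221	mirna-004	0	+
chr4	94587850	94587870	mirna-005	0	+
chr2	74146900	74146922	mirna-006	0	-
chr1	9803700	9803722	mirna-007	0	+
chr4	8243900	8243923	mirna-008	0	+
chr5	16600900	16600996	yrna-001	0	+
chr2	99119750	99119846	yrna-002	0	+
chr5	26661100	26661196	yrna-003	0	-
chr4	41070150	41070223	trna-001	0	-
chr2	6517550	6517623	trna-002	0	+
chr3	95433550	95433623	trna-003	0	-
chr5	69434750	69434870	rrna-001	0	+
chr6	74049750	74049870	rrna-002	0	+
chr6	40688550	40688656	snrna-001	0	-
chr3	59654100	59654206	snrna-002	0	-
chr3	96936800	96936880	snorna-001	0	+
chr8	35228100	35228180	snorna-002	0	-
chr2	9800500	9800526	pirna-001	0	-
chr4	71023700	71023726	pirna-002	0	+
chr8	57281600	57281628	pirna-003	0	+
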