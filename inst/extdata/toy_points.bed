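chrT	5	6
chrT	11	12
chrT	61	62
chrT	92	93
chrT	143	144
chrT	213	214
chrT	322	323
chrT	362	363
chrT	373	374
chrT	393	394
chrT	432	433
chrT	477	478
chrT	571	572
chrT	642	643
chrT	733	734
chrT	746	747
chrT	852	853
chrT	920	921
chrT	935	936
chrT	977	978
chrT	994	995
chrT	998	999
chrT	1062	1063
chrT	1116	1117
chrT	1136	1137
chrT	1186	1187
chrT	1236	1237
chrT	1313	1314
chrT	1517	1518
chrT	1572	1573
chrT	1580	1581
chrT	1582	1583
chrT	1743	1744
chrT	1761	1762
chrT	1931	1932
chrT	1982	1983
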