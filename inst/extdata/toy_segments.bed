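chrT	231	299
chrT	317	377
chrT	482	633
chrT	709	806
chrT	871	916
chrT	1044	1051
chrT	1354	1465
chrT	1510	1612
chrT	1660	1705
chrT	1816	1850
chrT	1861	1921
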