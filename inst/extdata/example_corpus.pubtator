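101|t|Tamoxifen response in breast cancer.
101|a|We report rs1042522 in cancer with TP53 involvement.
101	0	9	Tamoxifen	Chemical	MESH:D013629
101	29	35	cancer	Disease	MESH:D009369
101	47	56	rs1042522	SNP	rs1042522
101	60	66	cancer	Disease	MESH:D009369
101	72	76	TP53	Gene	7157

102|t|TP53 variants and cancers.
102|a|The variant rs1042522 was studied in cancers.
102	0	4	TP53	Gene	7157
102	18	25	cancers	Disease	MESH:D009369
102	39	48	rs1042522	SNP	rs1042522
102	64	71	cancers	Disease	MESH:D009369
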