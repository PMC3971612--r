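compound_id	name	monoisotopic_mass	source_db	kegg_pathways	origin_class
CPD0001	D-Glucose	180.063388	KEGG	ko00010,ko00500	mammalian
CPD0002	Butyric acid	88.052429	KEGG	ko00650	bacterial
CPD0003	Propionic acid	74.036779	KEGG	ko00640	bacterial
CPD0004	Acetic acid	60.021129	KEGG	ko00620	bacterial
CPD0005	L-Lactic acid	90.031694	KEGG	ko00620	bacterial
CPD0006	Nicotinate	123.032028	KEGG	ko00760	mammalian
CPD0007	L-Tryptophan	204.089878	KEGG	ko00380	mammalian
CPD0008	Glutathione	307.083806	KEGG	ko00480	mammalian
CPD0009	Cholic acid	408.287574	HMDB	ko00120	mammalian
CPD0010	Deoxycholic acid	392.29266	HMDB	ko00121	bacterial
CPD0011	Taurine	125.014664	KEGG	ko00430	mammalian
CPD0012	Spermidine	145.157898	KEGG	ko00330	mammalian
CPD0013	N1-Acetylspermidine	187.168462	HMDB	ko00330	mammalian
CPD0014	Succinic acid	118.026609	KEGG	ko00020	bacterial
CPD0015	Indole	117.057849	KEGG	ko00380	bacterial
CPD0016	p-Cresol	108.057515	HMDB	ko00350	bacterial
CPD0017	Histamine	111.079647	KEGG	ko00340	mammalian
CPD0018	L-Citrulline	175.095691	KEGG	ko00330	mammalian
CPD0019	Glycochenodeoxycholic acid	449.314123	LipidMaps	ko00121	mammalian
CPD0020	Urobilin	590.310435	HMDB	ko00860	mammalian
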