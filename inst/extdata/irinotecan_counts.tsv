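measure	term	database	count	denominator	digits	printed_pct
pt_share	diarrhoea	FAERS	1728	35747	2	4.83
pt_share	nausea	FAERS	888	35747	2	2.48
pt_share	vomiting	FAERS	813	35747	2	2.27
pt_share	disease progression	FAERS	765	35747	2	2.14
pt_share	neutropenia	FAERS	764	35747	2	2.14
pt_share	neutropenia	JADER	1176	14591	2	8.06
pt_share	diarrhoea	JADER	1053	14591	2	7.22
pt_share	neutrophil count decreased	JADER	1004	14591	2	6.88
pt_share	interstitial lung disease	JADER	811	14591	2	5.56
pt_share	febrile neutropenia	JADER	708	14591	2	4.85
sex	male	FAERS	5176	11344	1	45.6
sex	female	FAERS	3821	11344	1	33.7
sex	male	JADER	4724	7822	1	60.4
sex	female	JADER	2845	7822	1	36.4
age	18-65 years	FAERS	4307	11344	1	38.0
age	>65 years	FAERS	3312	11344	1	29.2
age	20-70 years	JADER	4615	7822	1	59.0
age	>70 years	JADER	2810	7822	1	35.9
weight	50-100 kg	FAERS	3311	11344	1	29.2
weight	50-100 kg	JADER	3229	7822	1	41.3
country	France	FAERS	1371	11344	1	12.1
country	Italy	FAERS	1109	11344	1	9.8
outcome	death	FAERS	2154	11344	1	19.0
outcome	hospitalization	FAERS	3359	11344	1	29.6
outcome	other serious	FAERS	4304	11344	1	37.9
outcome	death	JADER	1477	14591	1	10.1
indication	colorectal cancer metastatic	FAERS	1838	11344	1	16.2
indication	colon cancer	JADER	2229	7822	1	28.5
soc_share	general disorders and administration site conditions	FAERS	5401	35747	1	15.1
soc_share	blood and lymphatic system disorders	FAERS	2672	35747	1	7.5
soc_share	blood and lymphatic system disorders	JADER	3389	14591	1	23.2
soc_share	investigations	JADER	2499	14591	1	17.1
soc_share	nervous system disorders	FAERS	2799	35747	1	7.8
soc_share	skin and subcutaneous tissue disorders	FAERS	1726	35747	1	4.8
tto_bin	0-30	FAERS	2119	3988	1	53.1
tto_bin	31-60	FAERS	675	3988	1	16.9
tto_bin	61-90	FAERS	329	3988	1	8.2
tto_bin	>360	FAERS	111	3988	1	2.8
tto_bin	0-30	JADER	5366	8696	1	61.7
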