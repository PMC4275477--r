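query	query_fr	seconds	citations
Breast feeding	Allaitement maternel	0.42	633
Pharyngitis	Angine	0.53	845
Stroke	AVC	0.54	1704
COPD	BPCO	0.49	1503
Electronic cigarette	Cigarette électronique	0.42	24
Constipation	Constipation	0.27	531
Whooping cough	Coqueluche	0.54	314
Scabies	Gale	0.57	148
Hemochromatosis	Hémochromatose	0.59	712
Hypertension	Hypertension	1.03	8694
Lupus	Lupus	0.34	1147
Celiac disease	Maladie cœliaque	0.58	723
Crohn disease	Maladie de Crohn	0.69	1363
Nutrition	Nutrition	1.13	8367
Psychiatry	Psychiatrie	0.94	5602
Sarcoidosis	Sarcoïdose	0.77	1721
Scoliosis	Scoliose	1.1	669
Nursing care	Soins infirmiers	0.86	5767
Tobacco	Tabac	0.42	679
Toxoplasmosis	Toxoplasmose	0.74	1238
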