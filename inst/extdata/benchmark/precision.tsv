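query	strategy	strict	relaxed	retrieved
Breast feeding	babelmesh	0.55	0.75	20
Pharyngitis	babelmesh	0	0	20
Stroke	babelmesh	0.45	0.8	20
COPD	babelmesh	0.4	0.55	20
Electronic cigarette	babelmesh	0.1	0.1	20
Constipation	babelmesh	0.45	1	20
Whooping cough	babelmesh	0.8	1	20
Scabies	babelmesh	0.9	1	20
Hemochromatosis	babelmesh	0.65	0.95	20
Hypertension	babelmesh	0.45	0.75	20
Lupus	babelmesh	0.7	1	20
Celiac disease	babelmesh	0.7	0.95	20
Crohn disease	babelmesh	0.8	0.9	20
Nutrition	babelmesh	0.45	0.7	20
Psychiatry	babelmesh	0.75	0.8	20
Sarcoidosis	babelmesh	0.7	0.9	20
Scoliosis	babelmesh	0.65	0.9	20
Nursing care	babelmesh	0.85	0.9	20
Tobacco	babelmesh	0.6	0.9	20
Toxoplasmosis	babelmesh	0.65	0.9	20
Breast feeding	multilingual_french	1	1	20
Pharyngitis	multilingual_french	0.65	0.7	20
Stroke	multilingual_french	0.95	0.95	20
COPD	multilingual_french	1	1	20
Electronic cigarette	multilingual_french	0.35	0.4	20
Constipation	multilingual_french	1	1	20
Whooping cough	multilingual_french	1	1	20
Scabies	multilingual_french	1	1	20
Hemochromatosis	multilingual_french	1	1	20
Hypertension	multilingual_french	0.95	0.95	20
Lupus	multilingual_french	1	1	20
Celiac disease	multilingual_french	1	1	20
Crohn disease	multilingual_french	1	1	20
Nutrition	multilingual_french	0.7	1	20
Psychiatry	multilingual_french	1	1	20
Sarcoidosis	multilingual_french	1	1	20
Scoliosis	multilingual_french	1	1	20
Nursing care	multilingual_french	1	1	20
Tobacco	multilingual_french	1	1	20
Toxoplasmosis	multilingual_french	1	1	20
Breast feeding	pubmed_lifo	1	1	3
Pharyngitis	pubmed_lifo	0	0	20
Stroke	pubmed_lifo	0.15	0.15	20
COPD	pubmed_lifo	0.75	0.85	20
Electronic cigarette	pubmed_lifo	NA	NA	0
Constipation	pubmed_lifo	0.5	0.95	20
Whooping cough	pubmed_lifo	1	1	2
Scabies	pubmed_lifo	0.25	0.25	4
Hemochromatosis	pubmed_lifo	0.7	1	20
Hypertension	pubmed_lifo	0.25	0.75	20
Lupus	pubmed_lifo	0.75	0.95	20
Celiac disease	pubmed_lifo	1	1	2
Crohn disease	pubmed_lifo	0.5	1	2
Nutrition	pubmed_lifo	0.25	0.6	20
Psychiatry	pubmed_lifo	0.85	0.95	20
Sarcoidosis	pubmed_lifo	0.92	0.92	13
Scoliosis	pubmed_lifo	0.67	0.67	3
Nursing care	pubmed_lifo	0.7	0.8	20
Tobacco	pubmed_lifo	0.83	0.89	18
Toxoplasmosis	pubmed_lifo	1	1	10
Breast feeding	pubmed_relevance	1	1	3
Pharyngitis	pubmed_relevance	0	0	20
Stroke	pubmed_relevance	0.35	0.35	20
COPD	pubmed_relevance	1	1	20
Electronic cigarette	pubmed_relevance	NA	NA	0
Constipation	pubmed_relevance	0.75	1	20
Whooping cough	pubmed_relevance	1	1	2
Scabies	pubmed_relevance	0.25	0.25	4
Hemochromatosis	pubmed_relevance	0.85	1	20
Hypertension	pubmed_relevance	1	1	20
Lupus	pubmed_relevance	1	1	20
Celiac disease	pubmed_relevance	1	1	2
Crohn disease	pubmed_relevance	0.5	1	2
Nutrition	pubmed_relevance	1	1	20
Psychiatry	pubmed_relevance	0.9	0.95	20
Sarcoidosis	pubmed_relevance	0.92	0.92	13
Scoliosis	pubmed_relevance	0.67	0.67	3
Nursing care	pubmed_relevance	0.85	0.9	20
Tobacco	pubmed_relevance	0.83	0.89	18
Toxoplasmosis	pubmed_relevance	1	1	10
Breast feeding	pubmed_tt	1	1	20
Pharyngitis	pubmed_tt	0.5	0.6	20
Stroke	pubmed_tt	1	1	20
COPD	pubmed_tt	1	1	20
Electronic cigarette	pubmed_tt	NA	NA	0
Constipation	pubmed_tt	1	1	20
Whooping cough	pubmed_tt	1	1	20
Scabies	pubmed_tt	1	1	20
Hemochromatosis	pubmed_tt	1	1	20
Hypertension	pubmed_tt	1	1	20
Lupus	pubmed_tt	1	1	20
Celiac disease	pubmed_tt	1	1	20
Crohn disease	pubmed_tt	1	1	20
Nutrition	pubmed_tt	1	1	20
Psychiatry	pubmed_tt	1	1	20
Sarcoidosis	pubmed_tt	1	1	20
Scoliosis	pubmed_tt	1	1	20
Nursing care	pubmed_tt	1	1	20
Tobacco	pubmed_tt	1	1	20
Toxoplasmosis	pubmed_tt	1	1	20
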