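block	variable	CON	PAS	SED
fermentation	pH	6.86	6.77	0.052
fermentation	ammonia_N	26.8	105	6.285
fermentation	total_VFA	87.7	59.4	3.284
fermentation	acetate	71.4	59.4	0.963
fermentation	propionate	15.4	20.1	1.053
fermentation	butyrate	9.39	13.5	0.240
fermentation	iso_butyrate	1.70	2.23	0.106
fermentation	valerate	0.69	1.36	0.035
fermentation	iso_valerate	1.14	2.15	0.080
fermentation	caproate	0.25	0.75	0.096
fermentation	iso_caproate	0.01	0.44	0.027
fermentation	lactate	11.9	5.91	1.561
fermentation	DL_lactate_ratio	0.30	2.25	0.036
fermentation	H2_production	173	117	6.200
fermentation	protozoa_log	5.32	5.93	0.046
alpha_bacteria	richness	1940	2161	73.77
alpha_bacteria	shannon	6.10	6.35	0.080
alpha_bacteria	evenness	0.81	0.83	0.008
alpha_bacteria	simpson	0.99	0.99	0.001
alpha_bacteria	goods	0.93	0.92	0.004
alpha_methanogen	richness	25.4	28.0	0.668
alpha_methanogen	shannon	2.33	2.27	0.054
alpha_methanogen	evenness	0.72	0.68	0.014
alpha_methanogen	simpson	0.84	0.83	0.012
alpha_methanogen	goods	0.86	0.79	0.020
alpha_fungus	richness	66.7	87.6	6.906
alpha_fungus	shannon	1.37	1.97	0.079
alpha_fungus	evenness	0.33	0.44	0.016
alpha_fungus	simpson	0.61	0.73	0.025
alpha_fungus	goods	0.75	0.76	0.043
protozoa_pct	Entodiniinae	89.6	90.8	1.511
protozoa_pct	Diplodiniinae	2.65	1.87	0.787
protozoa_pct	Isotricha	0.50	0.69	0.249
protozoa_pct	Dasytricha	7.21	6.65	1.078
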