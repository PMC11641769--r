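protein_id	domain_index	start	end	score
Organelle_01	1	15	94	NA
Organelle_01	2	109	188	NA
Organelle_01	3	212	291	NA
Organelle_02	1	23	102	NA
Organelle_02	2	127	206	NA
Organelle_02	3	225	304	NA
Organelle_03	1	20	99	NA
Organelle_03	2	112	191	NA
Organelle_03	3	206	285	NA
Organelle_04	1	23	102	NA
Organelle_04	2	122	201	NA
Organelle_04	3	225	304	NA
Organelle_05	1	11	90	NA
Organelle_05	2	115	194	NA
Organelle_05	3	208	287	NA
OtherBac_01	1	11	90	NA
OtherBac_01	2	103	182	NA
OtherBac_01	3	208	287	NA
OtherBac_02	1	24	103	NA
OtherBac_02	2	121	200	NA
OtherBac_02	3	225	304	NA
OtherBac_03	1	20	99	NA
OtherBac_03	2	111	190	NA
OtherBac_03	3	208	287	NA
OtherBac_04	1	13	92	NA
OtherBac_04	2	116	195	NA
OtherBac_04	3	206	285	NA
OtherBac_05	1	18	97	NA
OtherBac_05	2	123	202	NA
OtherBac_05	3	221	300	NA
SourceBac_01	1	18	97	NA
SourceBac_01	2	121	200	NA
SourceBac_01	3	216	295	NA
SourceBac_02	1	15	94	NA
SourceBac_02	2	114	193	NA
SourceBac_02	3	219	298	NA
SourceBac_03	1	13	92	NA
SourceBac_03	2	105	184	NA
SourceBac_03	3	208	287	NA
SourceBac_04	1	14	93	NA
SourceBac_04	2	117	196	NA
SourceBac_04	3	214	293	NA
SourceBac_05	1	22	101	NA
SourceBac_05	2	125	204	NA
SourceBac_05	3	230	309	NA
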