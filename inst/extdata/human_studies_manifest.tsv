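study_id	n_young	n_old	age_young	age_old	tissue
GSE144304	26	54	20-27	75-90	vastus lateralis
GSE157585	21	30	20-30	65-91	vastus lateralis
GSE117525	51	47	18-29	65-96	vastus lateralis
GSE8479	26	25	18-28	65-84	vastus lateralis
GSE362&GSE674	14	16	20-29	65-75	vastus lateralis
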