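gene	disease	confidence	source	placeholder
APOE	AD	high	neuner2020	FALSE
APP	AD	high	neuner2020	FALSE
PSEN1	AD	high	neuner2020	FALSE
PSEN2	AD	high	neuner2020	FALSE
TREM2	AD	high	neuner2020	FALSE
BIN1	AD	high	neuner2020	FALSE
AD_GENE_07	AD	high	neuner2020	TRUE
AD_GENE_08	AD	high	neuner2020	TRUE
AD_GENE_09	AD	high	neuner2020	TRUE
AD_GENE_10	AD	high	neuner2020	TRUE
AD_GENE_11	AD	high	neuner2020	TRUE
AD_GENE_12	AD	high	neuner2020	TRUE
AD_GENE_13	AD	high	neuner2020	TRUE
AD_GENE_14	AD	high	neuner2020	TRUE
AD_GENE_15	AD	high	neuner2020	TRUE
AD_GENE_16	AD	high	neuner2020	TRUE
AD_GENE_17	AD	high	neuner2020	TRUE
AD_GENE_18	AD	high	neuner2020	TRUE
SNCA	PD	very_high	blauwendraat2020	FALSE
LRRK2	PD	very_high	blauwendraat2020	FALSE
GBA1	PD	very_high	blauwendraat2020	FALSE
RAB32	PD	emerging	rab32_reports	FALSE
PD_GENE_05	PD	high	blauwendraat2020	TRUE
PD_GENE_06	PD	high	blauwendraat2020	TRUE
PD_GENE_07	PD	high	blauwendraat2020	TRUE
PD_GENE_08	PD	high	blauwendraat2020	TRUE
PD_GENE_09	PD	high	blauwendraat2020	TRUE
PD_GENE_10	PD	high	blauwendraat2020	TRUE
PD_GENE_11	PD	high	blauwendraat2020	TRUE
PD_GENE_12	PD	high	blauwendraat2020	TRUE
PD_GENE_13	PD	high	blauwendraat2020	TRUE
PD_GENE_14	PD	high	blauwendraat2020	TRUE
PD_GENE_15	PD	high	blauwendraat2020	TRUE
MAPT	FTD	ge1pct_frequency	antonioni2023	FALSE
C9orf72	FTD	ge1pct_frequency	antonioni2023	FALSE
GRN	FTD	ge1pct_frequency	antonioni2023	FALSE
FTD_GENE_04	FTD	ge1pct_frequency	antonioni2023	TRUE
FTD_GENE_05	FTD	ge1pct_frequency	antonioni2023	TRUE
FTD_GENE_06	FTD	ge1pct_frequency	antonioni2023	TRUE
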