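cell_line	mirna_id	gmean_treated	gmean_control	fold_change
BT474	hsa-miR-34c-3p	76.9	10	7.69
BT474	hsa-miR-588	85.79	14.4	5.96
BT474	hsa-miR-580	58.94	10	5.89
BT474	hsa-miR-374a-3p	175.49	29.84	5.88
BT474	hsa-miR-616-3p	62.19	10.83	5.74
BT474	hsa-miR-3124-3p	166.41	29.76	5.59
BT474	hsa-miR-5088	307.06	56.29	5.46
BT474	hsa-miR-541-5p	97.02	19.1	5.08
BT474	hsa-miR-493-3p	83.25	16.82	4.95
BT474	hsa-miR-551b-5p	83.11	17.34	4.79
BT474	hsa-miR-466	33.72	299.95	-8.90
BT474	hsa-miR-5692a	12.15	102.61	-8.45
BT474	hsa-miR-99a-3p	18.39	123.48	-6.71
BT474	hsa-miR-379-3p	29.91	200.03	-6.69
BT474	hsa-miR-3671	11.07	62.79	-5.67
BT474	hsa-miR-937-3p	13.98	77.8	-5.57
BT474	hsa-miR-876-5p	16.9	89.68	-5.31
BT474	hsa-miR-1228-5p	17.77	90.27	-5.08
BT474	hsa-miR-300	20.41	102.78	-5.04
BT474	hsa-miR-6502-3p	19.4	97.29	-5.01
SKBR3	hsa-miR-580	185.53	11.47	16.18
SKBR3	hsa-miR-338-5p	125.93	11.94	10.54
SKBR3	hsa-miR-5196-5p	215.5	24.32	8.86
SKBR3	hsa-miR-4768-3p	129.57	16.88	7.68
SKBR3	hsa-miR-92b-5p	78.06	10.56	7.39
SKBR3	hsa-miR-4754	199.53	27.21	7.33
SKBR3	hsa-miR-890	67.76	10.02	6.76
SKBR3	hsa-miR-6716-5p	97.1	15.48	6.27
SKBR3	hsa-miR-613	149.1	23.91	6.24
SKBR3	hsa-miR-5090	527.56	85.64	6.16
SKBR3	hsa-miR-200a-3p	24.74	520.28	-21.03
SKBR3	hsa-miR-339-3p	43.85	763.4	-17.41
SKBR3	hsa-miR-345-5p	18.87	296.55	-15.72
SKBR3	hsa-miR-19a-5p	24.05	233.07	-9.69
SKBR3	hsa-miR-4760-5p	11.64	108.72	-9.34
SKBR3	hsa-miR-3684	20.84	162.31	-7.79
SKBR3	hsa-miR-190a	34.15	254.61	-7.46
SKBR3	hsa-miR-514a-5p	20.39	139.41	-6.84
SKBR3	hsa-miR-3976	25.61	161.05	-6.29
SKBR3	hsa-miR-10b-5p	39.53	239.88	-6.07
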