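name	hatch_mean	hatch_sd	d1_mean	d1_sd	d3_mean	d3_sd	d5_mean	d5_sd	corrected_ck	corrected_eyfp
CK	97.15	2.89	1.00	1.73	9.67	2.31	11.00	1.00	NA	NA
CK-b	80.68	7.28	2.67	2.52	10.50	3.54	13.00	4.24	NA	NA
dsEYFP	75.26	11.37	5.33	1.15	10.00	2.00	14.67	5.03	NA	NA
DS2	18.41	11.18	14.67	5.86	46.6	14.74	95.00	5.20	94.38	94.14
DS3	58.94	18.89	22.00	2.00	23.3	17.24	87.33	11.72	85.77	85.16
DS5	49.97	5.81	26.00	5.29	40.00	7.21	40.00	7.21	32.58	29.68
DS6	57.61	18.89	31.6	12.52	45.7	12.31	77.42	3.83	74.63	73.54
DS10	60.67	19.14	24.86	6.68	72.9	12.89	100.00	0.00	100.00	100.00
DS12	43.92	2.13	22.08	7.61	57.3	13.18	83.08	5.03	80.99	80.17
DS28	49.72	8.11	26.3	13.35	84.86	6.41	93.29	2.51	92.46	92.13
DS30	41.04	19.63	29.59	4.11	57.21	8.68	77.27	2.29	74.46	73.36
DS34	36.68	10.78	46.0	10.63	82.71	4.70	82.87	10.41	80.76	79.93
DS35	40.30	14.09	41.66	7.77	86.7	11.72	91.55	7.62	90.51	90.10
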