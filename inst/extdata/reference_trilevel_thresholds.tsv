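sample_id	low_count	low	moderate_count	high_count	high	total
Adipose	3101	1.20	8505	1313	19.99	12919
Brain	2949	1.22	8903	1553	13.14	13405
Breast	3311	1.18	8985	1289	17.66	13585
Cerebral Cortex	3385	0.66	9094	1522	9.47	14001
Colon	3402	1.18	8570	1300	18.00	13272
Heart	2855	0.88	7950	1386	9.99	12191
Kidney	2868	0.80	8991	1710	8.58	13695
Liver	2895	0.85	7679	1509	12.30	12083
Lung	3399	0.71	9111	1482	9.99	13992
Lymph Node	3229	1.19	8994	1656	14.43	13879
Muscle	4769	1.18	5872	1072	18.69	11713
Testis	2538	0.93	10425	3004	11.75	15967
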