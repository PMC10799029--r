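# Published worked-example rows: per-sample gene expression, competing-factor
# scores, the winning score (cf_max) and its risk probability (p_max), for
# four samples in each of four cohorts (datasets 1, 2, 3 and 7).
# cf_* and p_max are kept verbatim as printed so that display precision is
# preserved; label 1 = tumor, 0 = control.
dataset	sample_id	label	APP	CXCL8	PSMC2	SLC20A1	cf_1	cf_2	cf_3	cf_max	p_max
1	TCGA-AA-3522-11	0	14.46	2.57	10.12	12.36	-4.05384	-6.10284	NA	-4.05384	0.01706
1	TCGA-AA-3518-11	0	14.71	2.84	9.95	12.12	-4.08397	-6.24816	NA	-4.08397	0.016562
1	TCGA-DM-A1DA-01	1	13.32	5.64	10.92	9.79	-0.68019	0.829748	NA	0.829748	0.696302
1	TCGA-AD-6965-01	1	14.11	5.66	11.10	10.39	2.072846	0.802252	NA	2.072846	0.888236
2	TCGA-AA-3511-11A	0	7.865804	0.840519	4.230288	3.752095	-1.66003	-1.22637	NA	-1.22637	0.226818
2	TCGA-AA-3517-11A	0	7.346597	0.735178	4.032976	6.230919	-9.56825	-9.26049	NA	-9.26049	9.51E-05
2	TCGA-AZ-4323-01A	1	6.716108	5.586939	4.427988	3.826772	4.067608	4.417109	NA	4.417109	0.988075
2	TCGA-AA-3971-01A	1	7.566649	4.029144	5.304325	3.394695	5.079653	8.352782	NA	8.352782	0.999764
3	1353	0	10.90443	4.798452	9.339269	9.580673	-1.15919	-5.59369	-9.92037	-1.15919	0.238814
3	1354	0	10.95167	8.181189	9.176233	9.897567	-1.91304	-6.76058	-0.59102	-0.59102	0.356402
3	1961	1	11.19171	9.436294	10.13665	9.334996	1.29651	-2.77754	11.05611	11.05611	0.999984
3	1962	1	11.05174	11.19743	10.72173	9.063379	2.788005	-3.34919	21.23988	21.23988	1
7	1359-T	1	11.81	4.63	0.82	0.35	-2.54	0.03	8.46	8.46	1
7	1360-T	1	10.95	5.1	0.91	0.44	-1.17	-0.01	11.28	11.28	1
7	1368-N	0	0.45	0.2	1.4	3.19	-0.51	-3.92	-2.15	-0.51	0.38
7	1369-N	0	2.68	0.23	0.71	0.98	-3.93	-1.16	-5.79	-1.16	0.24
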