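# Published four-gene CRC competing-factor classifiers, one row per factor.
# Transcribed from the coefficient table of the published cross-cohort study
# (ten datasets: TCGA-COAD x2, GSE39582, GSE9348, GSE18105, GSE41258, a
# self-collected RT-PCR cohort, TCGA-READ, GSE103512, GSE156451).
# assignment: 'explicit' = gene-column mapping stated in the source text or
# forced by arity; 'inferred' = reconstructed from coefficient-sign rules
# (CXCL8/PSMC2 positive everywhere, SLC20A1 negative everywhere, APP positive
# in datasets 1,2,3,6 and negative in 5,7,8,9,10) and the stated gene
# combinations; numeric recomputation confirms dataset 1 only.
# note: dataset 2 printed per-sample factor values cannot be reconciled with
# any column assignment of its printed coefficients under the stated
# transforms; its rows are annotated 'inferred' and are not used for
# coefficient-level checks.
# 'Max' rows carry the combined classifier's metrics only.
dataset	source	n_tumor	n_control	factor	assignment	intercept	APP	CXCL8	PSMC2	SLC20A1	accuracy	sensitivity	specificity
1	TCGA-COAD-329	288	41	CF1	explicit	-90.3645	2.8598	NA	5.5149	-0.8795	86.02	85.07	92.68
1	TCGA-COAD-329	288	41	CF2	explicit	-26.5288	NA	0.5692	3.1516	-1.0474	95.74	96.18	92.68
1	TCGA-COAD-329	288	41	Max	explicit	NA	NA	NA	NA	NA	97.87	98.61	92.68
1	TCGA-COAD-329	288	41	CF_Stage1	explicit	-6.3439	NA	0.8358	NA	NA	85.71	90.70	80.49
2	TCGA-COAD-512	471	41	CF1	inferred	9.7471	3.8373	NA	3.4912	-14.1533	96.29	97.66	80.49
2	TCGA-COAD-512	471	41	CF2	inferred	-8.5448	NA	2.6917	17.7379	-13.4588	97.27	98.73	80.49
2	TCGA-COAD-512	471	41	Max	inferred	NA	NA	NA	NA	NA	98.24	99.79	80.49
2	TCGA-COAD-512	471	41	CF_Stage1	explicit	-11.1078	NA	5.7651	NA	NA	88.50	95.83	75.63
3	GSE39582	566	19	CF1	inferred	-44.7356	1.3067	NA	3.133	NA	89.40	89.22	94.74
3	GSE39582	566	19	CF2	inferred	-47.3452	NA	9.0331	NA	-5.8066	26.15	23.85	94.74
3	GSE39582	566	19	CF3	inferred	-28.1527	NA	3.4292	4.936	-4.6261	98.46	98.76	89.47
3	GSE39582	566	19	Max	inferred	NA	NA	NA	NA	NA	99.32	99.82	84.21
3	GSE39582	566	19	CF_Stage1	explicit	-4.0848	NA	0.5331	NA	NA	90.38	96.97	78.95
4	GSE9348	70	12	CF_Stage1	explicit	-0.2712	NA	0.0011	NA	NA	100	100	100
5	GSE18105	94	17	CF1	explicit	-3.1785	-4.3298	0.4519	4.305	-1.9872	99.10	100	94.12
6	GSE41258	186	54	CF1	inferred	-1.7889	0.6933	NA	11.5492	-0.1163	94.58	95.70	90.74
6	GSE41258	186	54	CF_Stage1	explicit	-2.9511	NA	0.0238	NA	NA	91.46	89.29	92.59
7	RT-PCR-CN	45	47	CF1	inferred	0.4565	-1.6293	NA	NA	NA	53.26	4.44	100
7	RT-PCR-CN	45	47	CF2	inferred	-0.4722	NA	1.3083	NA	-1.6565	64.13	35.56	91.49
7	RT-PCR-CN	45	47	CF3	inferred	-1.963	-1.677	NA	2.9094	NA	82.61	77.78	87.23
7	RT-PCR-CN	45	47	Max	inferred	NA	NA	NA	NA	NA	88.04	91.11	85.11
8	TCGA-READ	167	10	CF1	inferred	6.9125	NA	3.3834	NA	-5.007	72.32	71.26	90.00
8	TCGA-READ	167	10	CF2	inferred	-24.4459	-4.8627	NA	13.8489	NA	90.40	91.02	80.00
8	TCGA-READ	167	10	Max	inferred	NA	NA	NA	NA	NA	97.18	98.20	80
9	GSE103512	57	12	CF1	inferred	-16.337	-4.9005	NA	9.4632	-3.6135	85.51	84.21	91.67
9	GSE103512	57	12	CF2	inferred	-34.282	NA	3.456	2.9659	-2.0026	85.51	84.21	91.67
9	GSE103512	57	12	Max	inferred	NA	NA	NA	NA	NA	98.55	100	91.67
10	GSE156451	72	72	CF1	inferred	-11.7722	-0.0677	NA	3.1961	-0.8797	90.97	90.28	91.67
total	pooled	2016	325	Max	explicit	NA	NA	NA	NA	NA	97.74	98.81	91.08
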