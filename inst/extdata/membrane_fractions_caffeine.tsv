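variant_id	cpr_region	wt_reference_id	cyp_content	cyp_sd	cpr_content	cpr_sd	printed_ratio	stability_ratio	stability_sd	caffeine_consumed	consumed_sd	theophylline	theophylline_sd	theobromine	theobromine_sd	paraxanthine	paraxanthine_sd
T142A	FMN domain (natural variant)	Wt_A	145	2	38.5	0.9	1:4	1.01	0.13	5.82	0.18	0.85	0.10	0.39	0.01	4.58	0.15
Q153R	FMN domain (natural variant)	Wt_B	267	3	26.0	0.4	1:10	0.85	0.12	12.96	0.66	1.16	0.08	1.00	0.04	10.80	0.66
V164M	FMN domain (natural variant)	Wt_B	259	2	35.2	0.8	1:7	0.94	0.16	10.15	0.48	0.92	0.02	0.91	0.05	8.32	0.48
D211N	FMN domain (natural variant)	Wt_B	211	4	24.9	0.7	1:8	1.03	0.16	11.34	0.31	0.97	0.09	0.89	0.05	9.49	0.30
P228L	FMN domain (natural variant)	Wt_B	451	4	41.9	1.1	1:11	0.95	0.14	9.57	0.30	0.94	0.05	0.60	0.04	8.03	0.28
P117H	FMN domain (selected target)	Wt_C	148	1	12.2	0.5	1:12	0.93	0.14	9.29	0.30	0.79	0.03	0.53	0.06	7.97	0.30
G144C	FMN domain (selected target)	Wt_C	124	2	14.1	0.2	1:12	0.93	0.17	9.39	0.11	0.76	0.03	0.49	0.01	8.14	0.10
N151D	FMN domain (selected target)	Wt_C	446	4	27.7	0.5	1:12	1.02	0.13	8.85	0.07	0.82	0.50	0.63	0.02	7.40	0.05
G175D	FMN domain (selected target)	Wt_C	379	2	26.5	0.4	1:14	1.01	0.05	9.09	0.45	0.80	0.08	0.67	0.05	7.62	0.45
H183Y	FMN domain (selected target)	Wt_C	179	2	14.9	0.3	1:12	0.89	0.06	14.05	0.08	0.89	0.12	0.47	0.06	12.70	0.64
A229T	FMN domain (selected target)	Wt_A	71	4	17.3	0.2	1:4	0.99	0.11	13.30	0.28	0.86	0.12	1.04	0.15	11.40	0.52
S243P	hinge region (selected target)	Wt_B	73	4	7.7	0.2	1:9	0.60	0.06	9.81	0.06	0.46	0.07	0.44	0.05	8.92	0.40
I245P	hinge region (selected target)	Wt_C	102	1	6.1	0.5	1:17	0.98	0.12	7.28	0.09	0.38	0.06	0.73	0.08	6.17	0.28
R246A	hinge region (selected target)	Wt_C	91	2	5.4	0.2	1:17	0.84	0.06	11.89	0.23	0.62	0.09	1.02	0.13	10.25	0.54
Wt_A	wildtype	Wt_A	56	3	23.3	1.6	1:2	0.93	0.05	10.02	0.28	0.77	0.09	0.63	0.05	8.61	0.08
Wt_B	wildtype	Wt_B	116	3	12.4	0.8	1:9	0.88	0.07	10.25	0.23	0.80	0.10	0.63	0.05	8.81	0.20
Wt_C	wildtype	Wt_C	54	1	4.1	1.5	1:13	0.84	0.11	10.28	0.21	0.82	0.10	0.63	0.06	8.83	0.20
CPRnull	null	NA	85	3	ND	NA	NA	ND	NA	ND	NA	ND	NA	ND	NA	ND	NA
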