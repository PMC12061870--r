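drug	pt	n	ror	ror_lo	ror_hi	prr	chi2	ebgm	ebgm05	ic	ic025
adalimumab	Pulmonary thrombosis	741	2.35	2.18	2.54	2.35	530.25	2.24	2.11	1.17	-0.5
adalimumab	Cerebral thrombosis	163	1.88	1.61	2.21	1.88	63.09	1.83	1.6	0.87	-0.8
adalimumab	Postoperative thrombosis	144	10.39	8.57	12.58	10.39	885.18	7.8	6.64	2.96	1.29
adalimumab	Deep vein thrombosis postoperative	67	2.14	1.67	2.74	2.14	37.6	2.05	1.67	1.04	-0.63
adalimumab	Hepatic vascular thrombosis	28	6.33	4.19	9.54	6.33	101.95	5.32	3.78	2.41	0.73
adalimumab	Haemorrhoids thrombosed	26	3	2	4.5	3	31.22	2.8	2	1.49	-0.19
adalimumab	Injection site thrombosis	25	2.71	1.8	4.09	2.71	24.58	2.56	1.81	1.35	-0.32
adalimumab	Ophthalmic vein thrombosis	15	2.18	1.29	3.69	2.18	8.88	2.09	1.35	1.07	-0.61
adalimumab	Renal vascular thrombosis	12	2.52	1.4	4.56	2.52	10.1	2.39	1.46	1.26	-0.42
adalimumab	Splenic thrombosis	10	2.17	1.14	4.13	2.17	5.84	2.08	1.22	1.06	-0.62
adalimumab	Ophthalmic vascular thrombosis	6	6.56	2.69	15.99	6.56	22.81	5.48	2.6	2.46	0.71
adalimumab	Vascular pseudoaneurysm thrombosis	5	7.19	2.69	19.27	7.19	21.11	5.9	2.59	2.56	0.8
adalimumab	Postpartum thrombosis	4	36.45	8.16	162.86	36.45	59.1	16.19	4.63	4.02	2.06
adalimumab	Ophthalmic artery thrombosis	4	9.94	3.17	31.22	9.94	23.59	7.56	2.9	2.92	1.1
adalimumab	Thrombosis with thrombocytopenia syndrome	3	3.42	1.03	11.35	3.42	4.56	3.15	1.15	1.65	-0.1
adalimumab	Vaccination site thrombosis	1	13.67	1.24	150.74	13.67	7.83	9.45	1.27	3.24	1.04
adalimumab	Pseudothrombophlebitis	1	27.34	1.71	437.06	27.34	12.69	14.17	1.39	3.82	1.47
golimumab	Thrombophlebitis	15	2.27	1.37	3.78	2.27	10.65	2.27	1.48	1.18	-0.49
golimumab	Deep vein thrombosis postoperative	5	2.65	1.1	6.38	2.65	5.11	2.64	1.27	1.4	-0.27
golimumab	Retinal vascular thrombosis	4	4.07	1.52	10.88	4.07	9.18	4.04	1.77	2.02	0.34
golimumab	Cerebral artery thrombosis	3	3.21	1.03	10	3.21	4.54	3.2	1.24	1.68	0.01
golimumab	Application site thrombosis	1	54.13	6.86	427.25	54.13	46.93	48.81	8.66	5.61	3.73
golimumab	Shunt thrombosis	1	5.54	0.77	39.74	5.54	3.67	5.48	1.05	2.46	0.76
golimumab	Infective thrombosis	1	6.25	0.87	44.9	6.25	4.35	6.18	1.19	2.63	0.93
certolizumab pegol	Deep vein thrombosis postoperative	17	4.74	2.93	7.66	4.74	49.25	4.67	3.13	2.22	0.56
certolizumab pegol	Haemorrhoids thrombosed	5	4.9	2.02	11.88	4.9	15.23	4.83	2.3	2.27	0.6
certolizumab pegol	Application site thrombosis	1	28.1	3.56	221.83	28.1	23.52	25.39	4.51	4.67	2.79
etanercept	Deep vein thrombosis postoperative	34	1.46	1.04	2.05	1.46	4.71	1.44	1.08	0.53	-1.14
etanercept	Application site thrombosis	1	4.24	0.54	33.47	4.24	2.23	3.92	0.7	1.97	0.09
infliximab	Thrombophlebitis	67	1.42	1.12	1.81	1.42	8.17	1.41	1.15	0.5	-1.17
infliximab	Retinal vein thrombosis	16	1.7	1.03	2.79	1.7	4.47	1.68	1.11	0.75	-0.92
infliximab	Retinal vascular thrombosis	14	2	1.18	3.41	2	6.81	1.97	1.26	0.98	-0.69
infliximab	Haemorrhoids thrombosed	8	2.1	1.04	4.25	2.1	4.49	2.07	1.15	1.05	-0.63
infliximab	Subclavian artery thrombosis	5	3.42	1.39	8.4	3.42	8.15	3.3	1.56	1.72	0.03
infliximab	Infective thrombosis	5	4.53	1.83	11.21	4.53	12.88	4.31	2.02	2.11	0.41
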