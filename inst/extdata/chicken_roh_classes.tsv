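population	n_individuals	class_1	class_2	class_3	class_4	class_5	class_6	class_7	min_mb	max_mb	mean_mb	total_mb	mean_total_mb	sd_total_mb	mean_n	froh_mean
dual_purpose	49	182.37	34.83	5.61	0.16	0.00	0.00	0.00	0.30	5.48	0.71	7790.56	158.99	35.12	222.98	0.17
junglefowl	25	85.00	29.96	8.84	0.80	0.04	0.00	0.00	0.30	9.93	0.93	2903.82	116.15	95.21	124.64	0.12
broiler_a	20	149.65	29.85	6.10	0.35	0.05	0.00	0.00	0.30	8.56	0.74	2745.33	137.27	48.40	186.00	0.14
broiler_b	20	177.75	34.15	5.25	0.25	0.00	0.00	0.00	0.30	5.03	0.71	3085.30	154.26	18.56	217.40	0.16
layer_brown	23	315.17	86.39	23.22	2.57	0.00	0.04	0.00	0.30	10.42	0.86	8437.14	366.83	39.96	427.39	0.38
layer_white	24	389.04	98.13	24.13	1.25	0.00	0.00	0.00	0.30	6.42	0.81	9979.13	415.80	23.61	512.54	0.43
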