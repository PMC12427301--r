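taxon	pair	rl_mean	rl_sd	ci_mean	ci_sd	shape
Capri	1	7.5	0.8	39.0	2.4	M
Capri	2	6.8	0.4	40.9	1.7	M
Capri	3	6.8	0.6	32.3	1.2	sM
Capri	4	5.3	0.3	43.3	1.5	M
Capri	5	5.3	0.7	42.8	1.0	M
Capri	6	4.9	0.5	46.9	2.9	M
Capri	7	4.8	0.3	36.2	2.0	sM
Capri	8	4.8	0.8	22.4	2.5	sT
Capri	9	4.4	0.2	44.9	2.7	M
Capri	10	4.2	0.7	41.2	2.2	M
Capri	11	4.1	0.8	40.3	1.8	M
Capri	12	4.0	0.6	34.3	2.1	sM
Capri	13	3.8	0.6	39.5	1.7	M
Capri	14	3.8	0.4	33.6	1.6	sM
Capri	15	3.7	0.5	43.6	2.3	M
Capri	16	3.5	0.8	38.9	2.1	M
Capri	17	3.4	0.4	44.1	2.0	M
Capri	18	3.3	0.5	48.3	1.5	M
Capri	19	3.1	0.6	45.4	2.6	M
Capri	20	2.9	0.5	40.2	3.1	M
Capri	21	2.8	0.5	44.9	2.9	M
Capri	22	2.7	0.4	43.5	2.5	M
Capri	23	2.3	0.3	43.5	2.1	M
Capri	24	1.9	0.2	39.3	1.9	M
Palermo	1	7.7	0.7	39.8	2.9	M
Palermo	2	7.5	0.6	41.9	2.6	M
Palermo	3	6.3	0.7	35.1	2.0	sM
Palermo	4	5.3	0.5	42.5	2.7	M
Palermo	5	4.6	0.4	40.8	2.3	M
Palermo	6	4.4	0.6	46.3	2.5	M
Palermo	7	4.3	0.8	36.2	2.6	sM
Palermo	8	4.2	0.5	40.2	2.0	M
Palermo	9	4.1	0.6	43.8	2.4	M
Palermo	10	4.0	0.8	41.9	2.2	M
Palermo	11	3.8	0.4	41.8	2.9	M
Palermo	12	3.8	0.4	35.4	1.7	sM
Palermo	13	3.7	0.5	39.5	2.0	M
Palermo	14	3.6	0.7	33.9	1.6	sM
Palermo	15	3.6	0.6	45.4	1.9	M
Palermo	16	3.6	0.5	39.4	2.4	M
Palermo	17	3.5	0.6	35.1	2.2	sM
Palermo	18	3.5	0.9	49.1	2.1	M
Palermo	19	3.5	0.7	43.0	2.7	M
Palermo	20	3.3	0.3	39.7	2.0	M
Palermo	21	3.1	2.2	35.8	2.3	M
Palermo	22	3.1	2.0	40.3	2.7	M
Palermo	23	3.0	2.4	46.6	1.9	M
Palermo	24	2.5	2.7	39.4	2.0	M
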