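cv	features	participant	p_pct	pm_pct
loocv	rg	1	72	7
loocv	hr	1	74	6
loocv	ta	1	31	7
loocv	sc	1	49	7
loocv	rg	2	61	7
loocv	hr	2	57	7
loocv	ta	2	28	7
loocv	sc	2	69	7
loocv	rg	3	61	7
loocv	hr	3	45	7
loocv	ta	3	29	7
loocv	sc	3	84	5
loocv	rg	4	51	7
loocv	hr	4	60	7
loocv	ta	4	61	7
loocv	sc	4	51	7
loocv	rg	5	28	7
loocv	hr	5	93	4
loocv	ta	5	22	6
loocv	sc	5	69	7
loocv	rg	6	44	7
loocv	hr	6	94	3
loocv	ta	6	45	7
loocv	sc	6	61	7
loocv	rg	7	47	7
loocv	hr	7	82	6
loocv	ta	7	66	7
loocv	sc	7	60	7
loocv	rg	8	33	7
loocv	hr	8	77	6
loocv	ta	8	21	6
loocv	sc	8	61	7
loocv	rg	9	67	7
loocv	hr	9	77	6
loocv	ta	9	52	7
loocv	sc	9	18	6
loocv	rg	10	33	7
loocv	hr	10	62	7
loocv	ta	10	62	7
loocv	sc	10	76	6
loocv	rg	mean	50	15
loocv	hr	mean	72	16
loocv	ta	mean	42	18
loocv	sc	mean	60	18
loocv	rg+hr	1	76	6
loocv	rg+ta	1	83	6
loocv	rg+sc	1	69	7
loocv	hr+ta	1	86	5
loocv	hr+sc	1	71	7
loocv	ta+sc	1	64	7
loocv	rg+hr	2	73	6
loocv	rg+ta	2	82	6
loocv	rg+sc	2	73	6
loocv	hr+ta	2	61	7
loocv	hr+sc	2	70	7
loocv	ta+sc	2	78	6
loocv	rg+hr	3	77	6
loocv	rg+ta	3	60	7
loocv	rg+sc	3	81	6
loocv	hr+ta	3	52	7
loocv	hr+sc	3	92	4
loocv	ta+sc	3	90	4
loocv	rg+hr	4	59	7
loocv	rg+ta	4	64	7
loocv	rg+sc	4	72	7
loocv	hr+ta	4	70	7
loocv	hr+sc	4	68	7
loocv	ta+sc	4	87	5
loocv	rg+hr	5	92	4
loocv	rg+ta	5	46	7
loocv	rg+sc	5	54	7
loocv	hr+ta	5	93	4
loocv	hr+sc	5	84	5
loocv	ta+sc	5	76	6
loocv	rg+hr	6	94	3
loocv	rg+ta	6	69	7
loocv	rg+sc	6	64	7
loocv	hr+ta	6	93	4
loocv	hr+sc	6	96	3
loocv	ta+sc	6	71	7
loocv	rg+hr	7	84	5
loocv	rg+ta	7	66	7
loocv	rg+sc	7	64	7
loocv	hr+ta	7	86	5
loocv	hr+sc	7	86	5
loocv	ta+sc	7	66	7
loocv	rg+hr	8	74	6
loocv	rg+ta	8	48	7
loocv	rg+sc	8	61	7
loocv	hr+ta	8	76	6
loocv	hr+sc	8	71	7
loocv	ta+sc	8	64	7
loocv	rg+hr	9	82	6
loocv	rg+ta	9	72	7
loocv	rg+sc	9	64	7
loocv	hr+ta	9	78	6
loocv	hr+sc	9	73	6
loocv	ta+sc	9	49	7
loocv	rg+hr	10	67	7
loocv	rg+ta	10	54	7
loocv	rg+sc	10	67	7
loocv	hr+ta	10	73	6
loocv	hr+sc	10	77	6
loocv	ta+sc	10	81	6
loocv	rg+hr	mean	78	11
loocv	rg+ta	mean	64	13
loocv	rg+sc	mean	67	7
loocv	hr+ta	mean	77	14
loocv	hr+sc	mean	79	10
loocv	ta+sc	mean	73	12
loocv	rg+hr+ta	1	91	4
loocv	rg+hr+sc	1	79	6
loocv	rg+ta+sc	1	84	5
loocv	hr+ta+sc	1	92	4
loocv	rg+hr+ta+sc	1	92	4
loocv	rg+hr+ta	2	82	6
loocv	rg+hr+sc	2	78	6
loocv	rg+ta+sc	2	83	6
loocv	hr+ta+sc	2	75	6
loocv	rg+hr+ta+sc	2	82	6
loocv	rg+hr+ta	3	77	6
loocv	rg+hr+sc	3	93	4
loocv	rg+ta+sc	3	82	6
loocv	hr+ta+sc	3	92	4
loocv	rg+hr+ta+sc	3	93	4
loocv	rg+hr+ta	4	68	7
loocv	rg+hr+sc	4	69	7
loocv	rg+ta+sc	4	78	6
loocv	hr+ta+sc	4	82	6
loocv	rg+hr+ta+sc	4	83	6
loocv	rg+hr+ta	5	93	4
loocv	rg+hr+sc	5	84	5
loocv	rg+ta+sc	5	73	7
loocv	hr+ta+sc	5	84	5
loocv	rg+hr+ta+sc	5	84	5
loocv	rg+hr+ta	6	93	4
loocv	rg+hr+sc	6	97	3
loocv	rg+ta+sc	6	72	7
loocv	hr+ta+sc	6	98	2
loocv	rg+hr+ta+sc	6	98	2
loocv	rg+hr+ta	7	86	5
loocv	rg+hr+sc	7	87	5
loocv	rg+ta+sc	7	67	7
loocv	hr+ta+sc	7	89	4
loocv	rg+hr+ta+sc	7	90	4
loocv	rg+hr+ta	8	74	6
loocv	rg+hr+sc	8	75	6
loocv	rg+ta+sc	8	64	7
loocv	hr+ta+sc	8	71	7
loocv	rg+hr+ta+sc	8	74	6
loocv	rg+hr+ta	9	81	6
loocv	rg+hr+sc	9	80	6
loocv	rg+ta+sc	9	67	7
loocv	hr+ta+sc	9	76	6
loocv	rg+hr+ta+sc	9	81	6
loocv	rg+hr+ta	10	72	7
loocv	rg+hr+sc	10	77	6
loocv	rg+ta+sc	10	79	6
loocv	hr+ta+sc	10	79	6
loocv	rg+hr+ta+sc	10	78	6
loocv	rg+hr+ta	mean	82	9
loocv	rg+hr+sc	mean	82	8
loocv	rg+ta+sc	mean	75	7
loocv	hr+ta+sc	mean	84	9
loocv	rg+hr+ta+sc	mean	86	8
loso	rg+hr+ta	1	33	7
loso	rg+hr+sc	1	33	7
loso	rg+ta+sc	1	36	7
loso	hr+ta+sc	1	33	7
loso	rg+hr+ta+sc	1	33	7
loso	rg+hr+ta	2	67	7
loso	rg+hr+sc	2	37	7
loso	rg+ta+sc	2	58	7
loso	hr+ta+sc	2	64	7
loso	rg+hr+ta+sc	2	65	7
loso	rg+hr+ta	3	33	7
loso	rg+hr+sc	3	41	7
loso	rg+ta+sc	3	36	7
loso	hr+ta+sc	3	33	7
loso	rg+hr+ta+sc	3	36	7
loso	rg+hr+ta	4	47	7
loso	rg+hr+sc	4	36	7
loso	rg+ta+sc	4	33	7
loso	hr+ta+sc	4	49	7
loso	rg+hr+ta+sc	4	34	7
loso	rg+hr+ta	5	66	7
loso	rg+hr+sc	5	41	7
loso	rg+ta+sc	5	37	7
loso	hr+ta+sc	5	64	7
loso	rg+hr+ta+sc	5	38	7
loso	rg+hr+ta	6	36	7
loso	rg+hr+sc	6	34	7
loso	rg+ta+sc	6	33	7
loso	hr+ta+sc	6	34	7
loso	rg+hr+ta+sc	6	34	7
loso	rg+hr+ta	7	33	7
loso	rg+hr+sc	7	33	7
loso	rg+ta+sc	7	39	7
loso	hr+ta+sc	7	33	7
loso	rg+hr+ta+sc	7	33	7
loso	rg+hr+ta	8	34	7
loso	rg+hr+sc	8	53	7
loso	rg+ta+sc	8	51	7
loso	hr+ta+sc	8	54	7
loso	rg+hr+ta+sc	8	54	7
loso	rg+hr+ta	9	41	7
loso	rg+hr+sc	9	60	7
loso	rg+ta+sc	9	56	7
loso	hr+ta+sc	9	51	7
loso	rg+hr+ta+sc	9	66	7
loso	rg+hr+ta	10	48	7
loso	rg+hr+sc	10	48	7
loso	rg+ta+sc	10	48	7
loso	hr+ta+sc	10	36	7
loso	rg+hr+ta+sc	10	42	7
loso	rg+hr+ta	mean	44	13
loso	rg+hr+sc	mean	42	9
loso	rg+ta+sc	mean	43	10
loso	hr+ta+sc	mean	45	13
loso	rg+hr+ta+sc	mean	44	13
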