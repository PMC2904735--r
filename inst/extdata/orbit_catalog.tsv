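orbit	graphlet	nodes	edges	degree	multiplicity	o	weight
0	0	2	1	1	2	1	1.0000000000
1	1	3	2	1	2	2	0.8384445326
2	1	3	2	2	1	2	0.8384445326
3	2	3	3	2	3	4	0.6768890651
4	3	4	3	1	2	3	0.7439406423
5	3	4	3	2	2	4	0.6768890651
6	4	4	3	1	3	3	0.7439406423
7	4	4	3	3	1	3	0.7439406423
8	5	4	4	2	4	6	0.5823851749
9	6	4	4	1	1	5	0.6248798213
10	6	4	4	2	2	8	0.5153335977
11	6	4	4	3	1	7	0.5464564633
12	7	4	5	2	2	11	0.4411099078
13	7	4	5	3	2	12	0.4208297074
14	8	4	6	3	4	15	0.3688204636
15	9	5	4	1	2	4	0.6768890651
16	9	5	4	2	2	6	0.5823851749
17	9	5	4	2	1	5	0.6248798213
18	10	5	4	1	1	4	0.6768890651
19	10	5	4	1	2	5	0.6248798213
20	10	5	4	2	1	6	0.5823851749
21	10	5	4	3	1	6	0.5823851749
22	11	5	4	1	4	4	0.6768890651
23	11	5	4	4	1	4	0.6768890651
24	12	5	5	2	5	9	0.4878812846
25	13	5	5	1	1	7	0.5464564633
26	13	5	5	2	1	9	0.4878812846
27	13	5	5	2	2	12	0.4208297074
28	13	5	5	3	1	10	0.4633243538
29	14	5	5	1	1	6	0.5823851749
30	14	5	5	2	1	10	0.4633243538
31	14	5	5	2	2	12	0.4208297074
32	14	5	5	3	1	10	0.4633243538
33	15	5	5	1	2	9	0.4878812846
34	15	5	5	2	1	11	0.4411099078
35	15	5	5	3	2	14	0.3849009958
36	16	5	5	1	2	8	0.5153335977
37	16	5	5	2	2	12	0.4208297074
38	16	5	5	4	1	10	0.4633243538
39	17	5	6	2	3	14	0.3849009958
40	17	5	6	3	2	13	0.4021737316
41	18	5	6	2	2	21	0.2903971056
42	18	5	6	2	1	17	0.3396480300
43	18	5	6	3	2	24	0.2592742400
44	19	5	6	1	1	12	0.4208297074
45	19	5	6	2	1	19	0.3137240849
46	19	5	6	3	1	20	0.3017688864
47	19	5	6	3	2	24	0.2592742400
48	20	5	6	2	4	21	0.2903971056
49	20	5	6	4	1	13	0.4021737316
50	21	5	6	1	1	13	0.4021737316
51	21	5	6	2	2	23	0.2691938337
52	21	5	6	3	1	21	0.2903971056
53	21	5	6	4	1	20	0.3017688864
54	22	5	7	2	1	25	0.2497596425
55	22	5	7	3	2	36	0.1647703497
56	22	5	7	3	2	31	0.1996224993
57	23	5	7	2	2	37	0.1583843264
58	23	5	7	3	2	43	0.1233572611
59	23	5	7	4	1	32	0.1922226628
60	24	5	7	1	1	16	0.3537781302
61	24	5	7	3	3	37	0.1583843264
62	24	5	7	4	1	26	0.2406182641
63	25	5	7	2	3	27	0.2318219269
64	25	5	7	4	2	27	0.2318219269
65	26	5	8	3	4	55	0.0659897290
66	26	5	8	4	1	37	0.1583843264
67	27	5	8	2	1	42	0.1288416382
68	27	5	8	3	2	55	0.0659897290
69	27	5	8	4	2	56	0.0617900610
70	28	5	9	3	2	62	0.0380670318
71	28	5	9	4	3	69	0.0131344760
72	29	5	10	4	5	73	0.0000000000
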