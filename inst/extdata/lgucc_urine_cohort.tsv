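id	cytology	cystoscopy	recurrence	grade	CCNA1	CCND2	CALCA	any_positive
1	+	+	-	LGUCC	NA	-	-	-
2	+	+	-	LGUCC	NA	-	-	-
3	+	+	-	LGUCC	NA	-	-	-
4	+	-	-	LGUCC	NA	-	-	-
5	+	NA	-	LGUCC	NA	-	+	+
6	+	-	-	LGUCC	NA	-	+	+
7	+	+	+	LGUCC	NA	-	+	+
8	+	+	-	LGUCC	NA	-	-	-
9	+	NA	-	LGUCC	NA	-	-	-
10	+	-	NA	LGUCC	NA	+	+	+
11	+	+	-	LGUCC	NA	+	+	+
12	+	+	-	LGUCC	NA	+	+	+
13	+	NA	-	LGUCC	NA	-	+	+
14	+	+	NA	LGUCC	NA	-	-	-
15	+	+	+	LGUCC	-	-	+	+
16	+	+	+	LGUCC	NA	-	-	-
17	+	+	-	LGUCC	-	+	+	+
18	+	+	-	LGUCC	+	+	+	+
19	+	+	-	LGUCC	+	-	-	+
20	+	+	-	LGUCC	+	+	+	+
21	+	-	-	LGUCC	-	+	+	+
22	+	+	-	LGUCC	+	-	-	+
23	+	+	-	LGUCC	+	-	+	+
24	+	+	-	LGUCC	-	-	+	+
25	+	+	-	LGUCC	-	+	+	+
26	+	+	+	LGUCC	-	-	+	+
27	+	+	-	LGUCC	-	-	-	-
28	+	+	-	LGUCC	+	-	+	+
29	+	+	-	LGUCC	+	+	+	+
30	+	+	+	LGUCC	NA	-	-	-
31	+	+	-	LGUCC	+	-	+	+
32	+	+	-	LGUCC	+	-	+	+
33	+	-	NA	LGUCC	+	+	+	+
34	+	+	-	LGUCC	-	-	+	+
35	+	+	-	LGUCC	-	+	+	+
36	+	+	-	LGUCC	-	+	+	+
37	+	+	-	LGUCC	-	+	-	+
38	+	+	-	LGUCC	-	+	+	+
39	+	+	-	LGUCC	-	-	+	+
40	+	+	-	LGUCC	-	+	+	+
41	-	-	-	LGUCC	-	-	+	+
42	-	+	+	LGUCC	-	-	+	+
43	-	+	-	LGUCC	-	-	-	-
44	-	+	-	LGUCC	-	-	+	+
45	-	+	+	LGUCC	-	-	+	+
46	-	+	+	LGUCC	-	-	+	+
47	-	+	NA	LGUCC	-	-	+	+
48	-	-	-	LGUCC	-	-	+	+
49	-	+	-	LGUCC	+	-	+	+
50	-	+	+	LGUCC	-	-	-	-
51	-	+	-	LGUCC	-	-	-	-
52	-	+	-	LGUCC	+	-	+	+
53	-	+	-	LGUCC	+	-	-	+
54	-	-	+	LGUCC	+	-	+	+
55	-	+	+	LGUCC	+	+	+	+
56	-	+	+	LGUCC	+	-	+	+
57	-	+	-	LGUCC	-	-	-	-
58	-	+	-	LGUCC	+	+	+	+
59	-	+	-	LGUCC	-	-	-	-
60	-	+	-	LGUCC	+	+	+	+
61	-	+	-	LGUCC	+	-	+	+
62	-	+	-	LGUCC	+	-	+	+
63	-	+	-	LGUCC	+	-	+	+
64	-	+	-	LGUCC	-	-	+	+
65	-	+	-	LGUCC	-	-	+	+
66	-	+	-	LGUCC	+	+	+	+
67	-	+	-	LGUCC	NA	-	+	+
68	-	+	-	LGUCC	NA	+	+	+
69	-	+	-	LGUCC	NA	+	+	+
70	-	+	-	LGUCC	NA	+	+	+
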