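node_id	macroscale_region	functional_network	hemisphere	mni_x	mni_y	mni_z
0	prefrontal	n/a	L	0	0	0
1	prefrontal	n/a	R	0	0	0
2	prefrontal	n/a	L	0	0	0
3	prefrontal	n/a	R	0	0	0
4	prefrontal	n/a	L	0	0	0
5	prefrontal	n/a	R	0	0	0
6	prefrontal	n/a	L	0	0	0
7	prefrontal	n/a	R	0	0	0
8	prefrontal	n/a	L	0	0	0
9	prefrontal	n/a	R	0	0	0
10	prefrontal	n/a	L	0	0	0
11	prefrontal	n/a	R	0	0	0
12	prefrontal	n/a	L	0	0	0
13	prefrontal	n/a	R	0	0	0
14	prefrontal	n/a	L	0	0	0
15	prefrontal	n/a	R	0	0	0
16	prefrontal	n/a	L	0	0	0
17	prefrontal	n/a	R	0	0	0
18	prefrontal	n/a	L	0	0	0
19	prefrontal	n/a	R	0	0	0
20	prefrontal	n/a	L	0	0	0
21	prefrontal	n/a	R	0	0	0
22	prefrontal	n/a	L	0	0	0
23	prefrontal	n/a	R	0	0	0
24	prefrontal	n/a	L	0	0	0
25	prefrontal	n/a	R	0	0	0
26	prefrontal	n/a	L	0	0	0
27	prefrontal	n/a	R	0	0	0
28	prefrontal	n/a	L	0	0	0
29	prefrontal	n/a	R	0	0	0
30	prefrontal	n/a	L	0	0	0
31	prefrontal	n/a	R	0	0	0
32	prefrontal	n/a	L	0	0	0
33	prefrontal	n/a	R	0	0	0
34	prefrontal	n/a	L	0	0	0
35	prefrontal	n/a	R	0	0	0
36	prefrontal	n/a	L	0	0	0
37	prefrontal	n/a	R	0	0	0
38	prefrontal	n/a	L	0	0	0
39	prefrontal	n/a	R	0	0	0
40	prefrontal	n/a	L	0	0	0
41	prefrontal	n/a	R	0	0	0
42	prefrontal	n/a	L	0	0	0
43	prefrontal	n/a	R	0	0	0
44	prefrontal	n/a	L	0	0	0
45	prefrontal	n/a	R	0	0	0
46	motor	n/a	L	0	0	0
47	motor	n/a	R	0	0	0
48	motor	n/a	L	0	0	0
49	motor	n/a	R	0	0	0
50	motor	n/a	L	0	0	0
51	motor	n/a	R	0	0	0
52	motor	n/a	L	0	0	0
53	motor	n/a	R	0	0	0
54	motor	n/a	L	0	0	0
55	motor	n/a	R	0	0	0
56	motor	n/a	L	0	0	0
57	motor	n/a	R	0	0	0
58	motor	n/a	L	0	0	0
59	motor	n/a	R	0	0	0
60	motor	n/a	L	0	0	0
61	motor	n/a	R	0	0	0
62	motor	n/a	L	0	0	0
63	motor	n/a	R	0	0	0
64	motor	n/a	L	0	0	0
65	motor	n/a	R	0	0	0
66	motor	n/a	L	0	0	0
67	insular	n/a	R	0	0	0
68	insular	n/a	L	0	0	0
69	insular	n/a	R	0	0	0
70	insular	n/a	L	0	0	0
71	insular	n/a	R	0	0	0
72	insular	n/a	L	0	0	0
73	insular	n/a	R	0	0	0
74	parietal	n/a	L	0	0	0
75	parietal	n/a	R	0	0	0
76	parietal	n/a	L	0	0	0
77	parietal	n/a	R	0	0	0
78	parietal	n/a	L	0	0	0
79	parietal	n/a	R	0	0	0
80	parietal	n/a	L	0	0	0
81	parietal	n/a	R	0	0	0
82	parietal	n/a	L	0	0	0
83	parietal	n/a	R	0	0	0
84	parietal	n/a	L	0	0	0
85	parietal	n/a	R	0	0	0
86	parietal	n/a	L	0	0	0
87	parietal	n/a	R	0	0	0
88	parietal	n/a	L	0	0	0
89	parietal	n/a	R	0	0	0
90	parietal	n/a	L	0	0	0
91	parietal	n/a	R	0	0	0
92	parietal	n/a	L	0	0	0
93	parietal	n/a	R	0	0	0
94	parietal	n/a	L	0	0	0
95	parietal	n/a	R	0	0	0
96	parietal	n/a	L	0	0	0
97	parietal	n/a	R	0	0	0
98	parietal	n/a	L	0	0	0
99	parietal	n/a	R	0	0	0
100	parietal	n/a	L	0	0	0
101	temporal	n/a	R	0	0	0
102	temporal	n/a	L	0	0	0
103	temporal	n/a	R	0	0	0
104	temporal	n/a	L	0	0	0
105	temporal	n/a	R	0	0	0
106	temporal	n/a	L	0	0	0
107	temporal	n/a	R	0	0	0
108	temporal	n/a	L	0	0	0
109	temporal	n/a	R	0	0	0
110	temporal	n/a	L	0	0	0
111	temporal	n/a	R	0	0	0
112	temporal	n/a	L	0	0	0
113	temporal	n/a	R	0	0	0
114	temporal	n/a	L	0	0	0
115	temporal	n/a	R	0	0	0
116	temporal	n/a	L	0	0	0
117	temporal	n/a	R	0	0	0
118	temporal	n/a	L	0	0	0
119	temporal	n/a	R	0	0	0
120	temporal	n/a	L	0	0	0
121	temporal	n/a	R	0	0	0
122	temporal	n/a	L	0	0	0
123	temporal	n/a	R	0	0	0
124	temporal	n/a	L	0	0	0
125	temporal	n/a	R	0	0	0
126	temporal	n/a	L	0	0	0
127	temporal	n/a	R	0	0	0
128	temporal	n/a	L	0	0	0
129	temporal	n/a	R	0	0	0
130	temporal	n/a	L	0	0	0
131	temporal	n/a	R	0	0	0
132	temporal	n/a	L	0	0	0
133	temporal	n/a	R	0	0	0
134	temporal	n/a	L	0	0	0
135	temporal	n/a	R	0	0	0
136	temporal	n/a	L	0	0	0
137	temporal	n/a	R	0	0	0
138	temporal	n/a	L	0	0	0
139	temporal	n/a	R	0	0	0
140	occipital	n/a	L	0	0	0
141	occipital	n/a	R	0	0	0
142	occipital	n/a	L	0	0	0
143	occipital	n/a	R	0	0	0
144	occipital	n/a	L	0	0	0
145	occipital	n/a	R	0	0	0
146	occipital	n/a	L	0	0	0
147	occipital	n/a	R	0	0	0
148	occipital	n/a	L	0	0	0
149	occipital	n/a	R	0	0	0
150	occipital	n/a	L	0	0	0
151	occipital	n/a	R	0	0	0
152	occipital	n/a	L	0	0	0
153	occipital	n/a	R	0	0	0
154	occipital	n/a	L	0	0	0
155	occipital	n/a	R	0	0	0
156	occipital	n/a	L	0	0	0
157	occipital	n/a	R	0	0	0
158	occipital	n/a	L	0	0	0
159	occipital	n/a	R	0	0	0
160	occipital	n/a	L	0	0	0
161	occipital	n/a	R	0	0	0
162	occipital	n/a	L	0	0	0
163	occipital	n/a	R	0	0	0
164	occipital	n/a	L	0	0	0
165	limbic	n/a	R	0	0	0
166	limbic	n/a	L	0	0	0
167	limbic	n/a	R	0	0	0
168	limbic	n/a	L	0	0	0
169	limbic	n/a	R	0	0	0
170	limbic	n/a	L	0	0	0
171	limbic	n/a	R	0	0	0
172	limbic	n/a	L	0	0	0
173	limbic	n/a	R	0	0	0
174	limbic	n/a	L	0	0	0
175	limbic	n/a	R	0	0	0
176	limbic	n/a	L	0	0	0
177	limbic	n/a	R	0	0	0
178	limbic	n/a	L	0	0	0
179	limbic	n/a	R	0	0	0
180	limbic	n/a	L	0	0	0
181	limbic	n/a	R	0	0	0
182	limbic	n/a	L	0	0	0
183	limbic	n/a	R	0	0	0
184	limbic	n/a	L	0	0	0
185	limbic	n/a	R	0	0	0
186	limbic	n/a	L	0	0	0
187	limbic	n/a	R	0	0	0
188	limbic	n/a	L	0	0	0
189	limbic	n/a	R	0	0	0
190	limbic	n/a	L	0	0	0
191	limbic	n/a	R	0	0	0
192	limbic	n/a	L	0	0	0
193	limbic	n/a	R	0	0	0
194	limbic	n/a	L	0	0	0
195	limbic	n/a	R	0	0	0
196	limbic	n/a	L	0	0	0
197	limbic	n/a	R	0	0	0
198	limbic	n/a	L	0	0	0
199	limbic	n/a	R	0	0	0
200	limbic	n/a	L	0	0	0
201	cerebellum	n/a	R	0	0	0
202	cerebellum	n/a	L	0	0	0
203	cerebellum	n/a	R	0	0	0
204	cerebellum	n/a	L	0	0	0
205	cerebellum	n/a	R	0	0	0
206	cerebellum	n/a	L	0	0	0
207	cerebellum	n/a	R	0	0	0
208	cerebellum	n/a	L	0	0	0
209	cerebellum	n/a	R	0	0	0
210	cerebellum	n/a	L	0	0	0
211	cerebellum	n/a	R	0	0	0
212	cerebellum	n/a	L	0	0	0
213	cerebellum	n/a	R	0	0	0
214	cerebellum	n/a	L	0	0	0
215	cerebellum	n/a	R	0	0	0
216	cerebellum	n/a	L	0	0	0
217	cerebellum	n/a	R	0	0	0
218	cerebellum	n/a	L	0	0	0
219	cerebellum	n/a	R	0	0	0
220	cerebellum	n/a	L	0	0	0
221	cerebellum	n/a	R	0	0	0
222	cerebellum	n/a	L	0	0	0
223	cerebellum	n/a	R	0	0	0
224	cerebellum	n/a	L	0	0	0
225	cerebellum	n/a	R	0	0	0
226	cerebellum	n/a	L	0	0	0
227	cerebellum	n/a	R	0	0	0
228	cerebellum	n/a	L	0	0	0
229	cerebellum	n/a	R	0	0	0
230	cerebellum	n/a	L	0	0	0
231	cerebellum	n/a	R	0	0	0
232	cerebellum	n/a	L	0	0	0
233	cerebellum	n/a	R	0	0	0
234	cerebellum	n/a	L	0	0	0
235	cerebellum	n/a	R	0	0	0
236	cerebellum	n/a	L	0	0	0
237	cerebellum	n/a	R	0	0	0
238	cerebellum	n/a	L	0	0	0
239	cerebellum	n/a	R	0	0	0
240	cerebellum	n/a	L	0	0	0
241	cerebellum	n/a	R	0	0	0
242	subcortical	n/a	L	0	0	0
243	subcortical	n/a	R	0	0	0
244	subcortical	n/a	L	0	0	0
245	subcortical	n/a	R	0	0	0
246	subcortical	n/a	L	0	0	0
247	subcortical	n/a	R	0	0	0
248	subcortical	n/a	L	0	0	0
249	subcortical	n/a	R	0	0	0
250	subcortical	n/a	L	0	0	0
251	subcortical	n/a	R	0	0	0
252	subcortical	n/a	L	0	0	0
253	subcortical	n/a	R	0	0	0
254	subcortical	n/a	L	0	0	0
255	subcortical	n/a	R	0	0	0
256	subcortical	n/a	L	0	0	0
257	subcortical	n/a	R	0	0	0
258	subcortical	n/a	L	0	0	0
259	brainstem	n/a	R	0	0	0
260	brainstem	n/a	L	0	0	0
261	brainstem	n/a	R	0	0	0
262	brainstem	n/a	L	0	0	0
263	brainstem	n/a	R	0	0	0
264	brainstem	n/a	L	0	0	0
265	brainstem	n/a	R	0	0	0
266	brainstem	n/a	L	0	0	0
267	brainstem	n/a	R	0	0	0
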