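seed	md5
0	e7ac90561696a3d3915afa5f46ba61fb
1	f1a7134b48a8660d425d07048575ca88
2	8f0f0920f034b5d5b097fe05999aad6b
3	ea87e15e2fcb21aa53d6a79d4330536d
4	68200a6fad19c46a0fac33a307957ccf
5	375c5cf3fea935413ac35441da530887
6	a772247101d83eb9e3328e68c7ec09b2
7	88cf105d61371c93dcaef2971a9d9e46
8	d555288604f6a267c57fac367452c22a
9	a7a83916a41c1880452cde7407285d25
10	65d9eb5e8369aa95e4fc556ed316f6a8
11	1673bd60d50ab5d070f0576866d56e90
12	f44423d9a8e97024ee0046bf357289f4
13	1f7bcc74935f620152b922fce48739ea
14	428c13894a310300a43443e1dcc93696
15	ece8664de90a3d74dfb2af06e5ffbb45
16	c09a5e06487b3d840e422b42060f2733
17	faeb31eda9478c0eedd7b3abbd97c2a7
18	5ba0521200a7be4686aaae155276bafe
19	6869e043c27fa0531898e084d31da645
20	2ab9bdd7e74b6392a95b645a66e6a475
21	44e92dc6a06680fe70259b2eeab6d44c
22	f60e84ff65fcf755e0954c211485237e
23	164d1ddfc1fb489191b9a4f5b23ebe75
24	140fb663d79d149cd01d08568122723f
25	1469f4fef129c5b89eb860ca9623b954
26	f4dfba0381731bb241f6c90ed927c029
27	3c55df097a8d18702910c305a0a330a2
28	46919e14064856a018810727edaa488b
29	8be59171926b3974f9e2d8c833d8cb82
30	433e048da222762f44fb7040c959626d
31	ab5860a28ea224dcf0355ca790790960
32	1e4c620920493a59e316ed4592c373af
33	e07327ffe13c55d5ad8665f854f7a97b
34	bd67e1a2a2ef115fbeb0609052817d63
35	cdaf44e03ddee85ea66b7b87d64cc835
36	f5f1b692901a6807c549aaf822c89bb1
37	4f965b8a0f14c27540e0123732e2dbdb
38	a7c226fbdee5af8f435307d8fa3e8c4f
39	4cb0a8386ea124a271015ebc97b41744
40	c0effa8993f930c9655363ae47e3fdbf
41	ca308c3e94eca9529702c1c4cf77fc85
42	01963d2c1e4b82e1c9e75b4e17d36422
43	bfc531d5dc805843ab5f693d3afa857c
44	b6712fd85392f357189d97203ee612a2
45	3c560c81bf0fa17990e853e455ce54e3
46	23795f65ecd24594a980bcccb121199e
47	036ee2d6802090dcce09e26087a1bc4e
48	97141cc881a79826c0773fbb6f679c14
49	4a1a052fabd5e3b8f606844e541f9e8a
50	1cd63bbc0e1e00267d1651348408b84a
51	4c8234e37946939ac1c5c77ab80a7b41
52	b80e1cc4608dd32329bed3185703bfe8
53	464da12dc775a39dc782d8f02101c5c6
54	3c3ff7ed6cc721c8bf03208acfa2679c
55	a65fa1fd1b8269e8113dcdc82083f025
56	29df757db1f753ecc6def27e28c0c2aa
57	6c5638f846b27dc755edd4d301d83459
58	1658319095d9508ad5b38b2dcd8e40e6
59	5c4c1c2c5421d6b7245bd6a4e0da8cbf
60	e19c7f35179f8a48418dcffd658a7353
61	323738309c54b888b8d75b85dd507e50
62	d0de796172ddbfa8472fbf79aad792fc
63	c4a3e5f88525c29d1097f9b05993eb48
64	89a164c019cda5f2a3ddeadc01157cc3
65	801a5c8e7f053319840c0b4bbf4bc101
66	6e62517549de825bac623e3089fdb7bd
67	21395b417518f2b0044cb579879158f4
68	dbddd15cbb63e82955ac96c9544ba610
69	81a5c907f62a0fe2ccd06a235ebbd16a
70	8aeb693fe63dc28a85f602e1e2efd351
71	7ffeed2941b5375b370a3f00b0353b44
72	aba9945df942c82326c6e6aa30f9e42f
73	102f4a3e5e41c068eb717499b071bdaa
74	bc7225b812bb6f9e0fb97349585da494
75	6d4766f95da1785280fcd50c1221d95f
76	cbd1abf62029696e48d87741edb89d50
77	79f1866b62697b4098b4b04af6ad8dc8
78	b06aef545c3d90e41c122ab6e029af24
79	11a069e50315c3a3ea8940e272518409
80	d4ca14060c14cf1073b8ebeb8c6c6157
81	b9e6ad8a9f05f1e6f550fcd72f99b20b
82	9c341087c861f9c461b53a310f168c18
83	8d17a26ffaea5b85cbf3307215a41b30
84	96a7cda0a77d888c367fd8a8a11e86dd
85	2f384b69fb7a507de6b1aec048144ca8
86	1f113746c7ad57f5ff228c60ca685dda
87	7cd22a2face53b15fab9174f3045cede
88	e052e1a9f67b259a95485f63a75931ed
89	a12345d97f1825a6294bb2dffd0180a2
90	539334e2fe35e20d1b554defcd5f2ef6
91	e21cb4126ff6b08786aca9a449f6725b
92	84056d25aa770a6d0820ec9efcf28c6c
93	26aa6bf78abd1947a602b16eb3ffe569
94	14f775f2b146a1814693ffb66003f034
95	f7fb1c5ab5ca5e92dffda3912ed4f9b9
96	f262c9e13bdbdee56a21426f72933d7f
97	1dc85a4c436a734e564fb4d15a161cff
98	04325392476bdab6917f3f39d7fde651
99	01e821fad4327ee26d901c9140ab4f94
100	9ae2b203c6029efffe4802fe9b339feb
101	79236f648830fa42a0c33c38c2242e20
102	2495222d99651e4aed6b4b64619b66a1
103	f4bf314ce2dfbe36e1065a8fb3979c7c
104	395439d543eb539c3b3b890deb3c7e9b
105	525e3665e7c14ae2157e24f8d85c46d6
106	3c2f0285c67b11399551eb8f1af074cc
107	b138f57e857a639a696d45209af718e2
108	f22ac6e9564289f4f76f4b2797ffe91a
109	805a01797f7cad3bd7bc937ac14c6a37
110	5a2a622df3462e3affe65580e07b6041
111	e804c484ba7408ed1d3bc80002d21b7d
112	174b2ac8f694fa965ca24abb5854e58d
113	141d184f181906741938b57acfc39d6a
114	81f61565c97929b2755f3e2ee0c6f99d
115	344c661fdbb96bdc7d5909418ab55bff
116	a14ef05352e875fdfaddc7acfac91fa6
117	9c647a3c9b08c74582206aa7fcbecfd3
118	2ce3c774977e874aba4a6d319e00013e
119	ab13abd38c5aef306b1b5e856bcc949f
120	fe62fc6b7391949423ccb8f85c141b3e
121	270b945faf1b4a9bb9ba14cd5e3a755f
122	dce9d43384b3d6c53a90fd0dee3878be
123	9182c7b90f41de9788972ca46f3ebaa4
124	8a5b087e88b3a65a7d74029e60d2b5b1
125	4b623743f2b99fc739ad6164058f9e4a
126	105646acfa9e6ac17e477d3f35c3dde1
127	f2f6e59952fd6023cd8c3acc1572d979
128	7b18c7f425edabc9afc1a4653bdaed5b
129	481b06c143c4229d7df0ad67b73ed3ca
130	0ffb7731b4dd9627b2fa0fd132f413f8
131	3cb8dec2394c8135c2b3c21625bcddae
132	af29066261f0a398de7ffafbde5e7991
133	c8367c639a38153f683bfc1b1854afaa
134	29a102695a95bad56a0778502812abba
135	dedb0a881bf9c39b0773a2d0329fca80
136	902f8d39362817b007ed61a2e15eaebe
137	4af387238eb47a02dfecae94866016b4
138	45f73292afd83062bf20c75db4f4a8bb
139	e3983e92a176170c43ddeeb9587dd4d7
140	77d2e917b43b80553e5cae17c3218c37
141	56389b22ed39f5c9fc16b26fec611a72
142	483ab5f4584a40496c76fd6a7cc2cdd3
143	284c1fa746e2c1a81a01ef7f9ac8e93e
144	fa17d6b4a1ab0458192ad25089e606bc
145	e5bacd7749f9955fb2f82d16729951f9
146	7a65ad0e6ab37989987c95fcb503c44b
147	ec03a67c0d0f7826ee86bb897176fe49
148	9b8d65ae7a68119f59ceb867a0d215c6
149	f7c0c60b5b30036758c77cf53f1c2c44
150	6ae1c4c6fadd3585de3cc8f306478123
151	6a50cbb16a537c693ff989592f6bb6d6
152	e7beb38d1e329ecd3d671deda1c7bf4a
153	d8f0a9ff1f5d41e53e854aed1e68554c
154	41f1349ef4c7faa9e1fc72b21fbd1f54
155	0189cda7babd578646fbf3e9eeb8f1d7
156	18903f37e735abeffba1bf23b8598cea
157	64b9f5dcb33355eb6b215319a0c61407
158	b838d560bc89bdc9b407891aaabcaf16
159	0bf01d2bd9687cf6c97a0890e75f20ea
160	bcbad4eec50ec56a11df959cdc081f8d
161	8719d8afb32f9673787356166d1ab672
162	0c2700fe47a598070bae2db13dd2d44c
163	b5ca170fa7ba46caf0403488eec8f098
164	698c004ae01517d8fab4049426c561ea
165	2d55217a2bd412b6df4eeb0bd30246b9
166	b0789e6224ecd6eb948183380e3c3a65
167	f5404ac678895e4ac5e414b8d6672057
168	7b040aa82995a3c846cf5ed8e9609a3c
169	ed48802b34adedb927154ba768848609
170	5ef9b5cdaf84aa6f17542bc47d2afbe5
171	f324d0c5979bdc3e5482cd8385a7e67a
172	4cdd23f396a2784971a57aa1232eb841
173	ecf658c344b9a1f38bd7dd1bacd8ea4d
174	3e6d7f732b9832f321deeb0d5307f4e8
175	9f6c83c3a647c30ae4703bf88eb1f75f
176	3c857a7f4f0477c2ce453d4211f5d716
177	f7b21acb4118084448388c7316cfbc88
178	38fe622a32cdca2da600abe82cdd5e8d
179	2e2f7535e2a537c37d4cf2735914fc63
180	5f7e13c3f3c2393e07b36a76417ee5ff
181	91c704878eac377179973cb0fc4eaab8
182	d1a453cbecc2409127ce1cf6339f8f08
183	4a2754ce4123248fe2ae9181d8b4c0e7
184	4bd24b8070e6d991e4b216a7175627ed
185	ca67fdfad67d03da754363993db0f790
186	d31f47c0aa6a42f05eb0f7f7c5162243
187	eb01a7d955c82dcf1603dcff6848ad4f
188	8ebfe73ba50b42150ce35ec3db7d88b4
189	1972dbed770bf4fd804231f02b1c8363
190	02b4f80bc6025420050dadfa09ecf8da
191	6244ef5331fe8f2f140b10663bf97912
192	80075bb5cf3471561035b32fa0c2d360
193	d0e4b9b836bb405d780a5ad17e9d7bae
194	91826a64f3f8c33cf52d0008d69378e7
195	e3f7c7c1ecc4ef86c7720e1317211363
196	ab2f1e43416d4b86f0347a747bdc9fd9
197	cb2ee55b8aee51ed3c64f5d0f8a1f03c
198	f4c12cc32aac74135b8e309caf658064
199	4f8eed8b3b3f2031ade16f0a75c7689c
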