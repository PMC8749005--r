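region_id	community
region1	Non-hub
region2	Sensory
region3	Non-hub
region4	Non-hub
region5	Sensory
region6	Associative
region7	Sensory
region8	Sensory
region9	Default
region10	Sensory
region11	Sensory
region12	Associative
region13	Sensory
region14	Default
region15	Non-hub
region16	Associative
region17	Non-hub
region18	Non-hub
region19	Non-hub
region20	Associative
region21	Associative
region22	Sensory
region23	Non-hub
region24	Sensory
region25	Non-hub
region26	Non-hub
region27	Non-hub
region28	Associative
region29	Associative
region30	Associative
region31	Associative
region32	Associative
region33	Associative
region34	Default
region35	Sensory
region36	Non-hub
region37	Sensory
region38	Non-hub
region39	Associative
region40	Default
region41	Associative
region42	Sensory
region43	Non-hub
region44	Non-hub
region45	Associative
region46	Sensory
region47	Sensory
region48	Associative
region49	Associative
region50	Non-hub
region51	Non-hub
region52	Non-hub
region53	Sensory
region54	Associative
region55	Associative
region56	Associative
region57	Sensory
region58	Sensory
region59	Sensory
region60	Default
region61	Non-hub
region62	Default
region63	Associative
region64	Sensory
region65	Non-hub
region66	Sensory
region67	Sensory
region68	Sensory
region69	Sensory
region70	Default
region71	Non-hub
region72	Default
region73	Associative
region74	Associative
region75	Sensory
region76	Non-hub
region77	Sensory
region78	Non-hub
region79	Non-hub
region80	Default
region81	Non-hub
region82	Default
region83	Non-hub
region84	Associative
region85	Default
region86	Associative
region87	Associative
region88	Associative
region89	Non-hub
region90	Associative
region91	Associative
region92	Associative
region93	Associative
region94	Non-hub
region95	Default
region96	Associative
region97	Sensory
region98	Non-hub
region99	Sensory
region100	Sensory
region101	Sensory
region102	Sensory
region103	Sensory
region104	Sensory
region105	Default
region106	Sensory
region107	Non-hub
region108	Sensory
region109	Associative
region110	Non-hub
region111	Default
region112	Default
region113	Sensory
region114	Sensory
region115	Default
region116	Default
region117	Non-hub
region118	Default
region119	Associative
region120	Associative
region121	Non-hub
region122	Sensory
region123	Sensory
region124	Associative
region125	Associative
region126	Default
region127	Default
region128	Associative
region129	Associative
region130	Non-hub
region131	Sensory
region132	Sensory
region133	Associative
region134	Associative
region135	Associative
region136	Sensory
region137	Sensory
region138	Default
region139	Non-hub
region140	Default
region141	Sensory
region142	Non-hub
region143	Sensory
region144	Default
region145	Default
region146	Associative
region147	Non-hub
region148	Associative
region149	Sensory
region150	Sensory
region151	Default
region152	Default
region153	Associative
region154	Sensory
region155	Non-hub
region156	Associative
region157	Non-hub
region158	Non-hub
region159	Associative
region160	Non-hub
region161	Default
region162	Default
region163	Sensory
region164	Non-hub
region165	Sensory
region166	Non-hub
region167	Associative
region168	Associative
region169	Default
region170	Sensory
region171	Default
region172	Default
region173	Default
region174	Sensory
region175	Default
region176	Non-hub
region177	Default
region178	Sensory
region179	Non-hub
region180	Associative
region181	Associative
region182	Non-hub
region183	Associative
region184	Sensory
region185	Sensory
region186	Sensory
region187	Sensory
region188	Non-hub
region189	Non-hub
region190	Non-hub
region191	Sensory
region192	Sensory
region193	Default
region194	Default
region195	Sensory
region196	Default
region197	Default
region198	Associative
region199	Associative
region200	Non-hub
region201	Default
region202	Sensory
region203	Non-hub
region204	Associative
region205	Associative
region206	Associative
region207	Sensory
region208	Sensory
region209	Associative
region210	Associative
region211	Non-hub
region212	Sensory
region213	Associative
region214	Default
region215	Default
region216	Non-hub
region217	Associative
region218	Associative
region219	Associative
region220	Associative
region221	Non-hub
region222	Sensory
region223	Sensory
region224	Non-hub
region225	Sensory
region226	Associative
region227	Associative
region228	Associative
region229	Sensory
region230	Default
region231	Default
region232	Non-hub
region233	Non-hub
region234	Default
region235	Non-hub
region236	Default
region237	Non-hub
region238	Associative
region239	Associative
region240	Non-hub
region241	Associative
region242	Associative
region243	Non-hub
region244	Associative
region245	Associative
region246	Associative
region247	Default
region248	Associative
region249	Associative
region250	Sensory
region251	Associative
region252	Sensory
region253	Default
region254	Non-hub
region255	Non-hub
region256	Non-hub
region257	Default
region258	Associative
region259	Non-hub
region260	Associative
region261	Non-hub
region262	Sensory
region263	Default
region264	Non-hub
region265	Associative
region266	Sensory
region267	Associative
region268	Associative
region269	Associative
region270	Non-hub
region271	Associative
region272	Default
region273	Non-hub
region274	Default
region275	Associative
region276	Sensory
region277	Sensory
region278	Associative
region279	Sensory
region280	Default
region281	Associative
region282	Non-hub
region283	Non-hub
region284	Associative
region285	Sensory
region286	Sensory
region287	Sensory
region288	Non-hub
region289	Default
region290	Default
region291	Non-hub
region292	Associative
region293	Sensory
region294	Non-hub
region295	Non-hub
region296	Sensory
region297	Associative
region298	Non-hub
region299	Non-hub
region300	Sensory
region301	Sensory
region302	Default
region303	Sensory
region304	Sensory
region305	Associative
region306	Default
region307	Default
region308	Non-hub
region309	Non-hub
region310	Non-hub
region311	Associative
region312	Associative
region313	Default
region314	Non-hub
region315	Associative
region316	Associative
region317	Sensory
region318	Non-hub
region319	Default
region320	Associative
region321	Default
region322	Non-hub
region323	Associative
region324	Sensory
region325	Sensory
region326	Sensory
region327	Sensory
region328	Sensory
region329	Associative
region330	Associative
region331	Sensory
region332	Associative
region333	Associative
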