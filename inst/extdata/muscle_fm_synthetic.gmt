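FM01	synthetic stand-in: components of the NMJ	g009	g029	g045	g046	g137	g188	g225	g234	g261	g321	g340	g367	g391	g433	g441
FM02	synthetic stand-in: synaptic basal lamina	g032	g159	g161	g166	g189	g191	g204	g213	g264	g266	g328	g357	g421	g468	g471
FM03	synthetic stand-in: post-synaptic ion channels	g027	g031	g041	g119	g165	g218	g280	g322	g324	g365	g378	g396	g415	g445	g466
FM04	synthetic stand-in: ion transporters and pumps	g101	g164	g194	g209	g311	g385	g402	g411	g443	g462	g478	g480	g489	g490	g491
FM05	synthetic stand-in: calcium dynamics/homeostasis	g017	g131	g143	g185	g249	g271	g287	g298	g318	g335	g373	g374	g394	g397	g476
FM06	synthetic stand-in: thin filament	g020	g024	g036	g085	g168	g174	g228	g300	g317	g348	g392	g412	g438	g484	g485
FM07	synthetic stand-in: thick filament	g057	g065	g075	g095	g100	g102	g117	g244	g260	g277	g345	g347	g432	g452	g463
FM08	synthetic stand-in: z-disc	g016	g025	g058	g087	g093	g132	g139	g158	g193	g236	g304	g307	g370	g379	g455
FM09	synthetic stand-in: cytoskeleton	g053	g077	g099	g126	g134	g177	g181	g197	g215	g281	g310	g332	g400	g419	g498
FM10	synthetic stand-in: extracellular matrix	g033	g111	g120	g121	g138	g151	g308	g354	g387	g425	g444	g460	g461	g465	g496
FM11	synthetic stand-in: glycolytic metabolism	g006	g010	g012	g038	g059	g147	g192	g253	g341	g344	g363	g364	g377	g409	g436
FM12	synthetic stand-in: oxidative metabolism	g023	g026	g028	g030	g043	g050	g076	g109	g128	g133	g150	g160	g201	g243	g329
FM13	synthetic stand-in: mitochondrial electron transport	g003	g013	g056	g062	g083	g086	g105	g140	g269	g274	g290	g323	g338	g349	g427
FM14	synthetic stand-in: small-molecule transporters	g062	g074	g176	g232	g239	g258	g278	g286	g319	g325	g407	g414	g428	g447	g487
FM15	synthetic stand-in: mitochondrial membranes	g002	g003	g008	g037	g224	g254	g288	g297	g350	g360	g383	g384	g406	g439	g451
FM16	synthetic stand-in: mitochondrial signaling	g052	g070	g079	g090	g142	g146	g216	g224	g293	g313	g352	g360	g362	g431	g487
FM17	synthetic stand-in: hypertrophy	g069	g072	g176	g198	g270	g272	g405	g406	g408	g423	g426	g440	g451	g472	g483
FM18	synthetic stand-in: atrophy	g015	g054	g146	g224	g248	g265	g270	g338	g346	g403	g406	g417	g451	g473	g483
FM19	synthetic stand-in: inflammation	g013	g064	g074	g269	g286	g293	g306	g313	g315	g371	g401	g448	g470	g483	g493
FM20	synthetic stand-in: myogenic and cell-cycle regulators	g015	g035	g040	g068	g073	g112	g122	g123	g268	g313	g349	g376	g447	g470	g495
FM21	synthetic stand-in: fiber type maintenance	g039	g070	g097	g115	g171	g206	g238	g257	g258	g259	g265	g326	g349	g398	g492
FM22	synthetic stand-in: angiogenesis	g013	g040	g060	g078	g107	g144	g219	g223	g291	g326	g384	g403	g413	g414	g492
FM23	synthetic stand-in: oxidative stress	g022	g040	g123	g152	g179	g206	g233	g238	g273	g283	g325	g366	g447	g448	g464
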