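drug_id	gene	approved
drug001	g158	0
drug001	g288	0
drug001	g416	0
drug002	g117	0
drug002	g447	0
drug002	g462	0
drug003	g015	1
drug003	g068	1
drug003	g349	1
drug004	g027	0
drug004	g125	0
drug004	g185	0
drug005	g234	0
drug005	g239	0
drug005	g475	0
drug006	g036	0
drug006	g317	0
drug006	g364	0
drug007	g001	0
drug007	g047	0
drug007	g286	0
drug008	g112	1
drug008	g302	1
drug008	g395	1
drug009	g111	0
drug009	g239	0
drug009	g345	0
drug010	g091	1
drug010	g375	1
drug010	g492	1
drug011	g083	1
drug011	g100	1
drug011	g467	1
drug012	g259	1
drug012	g261	1
drug012	g463	1
drug013	g224	1
drug013	g302	1
drug013	g386	1
drug014	g098	0
drug014	g199	0
drug014	g266	0
drug015	g177	1
drug015	g219	1
drug015	g416	1
drug016	g143	0
drug016	g157	0
drug016	g337	0
drug017	g237	1
drug017	g478	1
drug017	g484	1
drug018	g044	0
drug018	g311	0
drug018	g498	0
drug019	g087	0
drug019	g108	0
drug019	g293	0
drug020	g086	1
drug020	g149	1
drug020	g152	1
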