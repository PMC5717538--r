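node1	node2	score
g009	g029	0.9065851706825196
g009	g137	0.9902092691371217
g009	g159	0.9557938622497022
g009	g166	0.9456220140634104
g009	g188	0.9809629448875785
g009	g225	0.9350897793704643
g009	g234	0.9139378840941935
g009	g261	0.9296342243487016
g009	g321	0.885902697937563
g009	g322	0.9114393126778304
g009	g323	0.8855503597157076
g009	g433	0.9791831971285865
g009	g441	0.9285569263156503
g009	g472	0.8613729360187427
g029	g137	0.9460693154484033
g029	g166	0.9296806498756632
g029	g188	0.8872497655078768
g029	g225	0.9443894596071913
g029	g234	0.8988201978756115
g029	g261	0.8791368509689346
g029	g289	0.8748814810160548
g029	g321	0.9910074516246096
g029	g378	0.9788296080892905
g029	g433	0.9741954982234164
g029	g441	0.9060013188095764
g056	g299	0.9160973510565236
g088	g361	0.9219924030965194
g135	g056	0.9124170525791123
g135	g331	0.9152366017503664
g135	g483	0.9881697625853121
g137	g188	0.913386452589184
g137	g225	0.8725561726046726
g137	g234	0.9277371462760493
g137	g321	0.8977384409308433
g137	g323	0.9921953188814223
g137	g324	0.8989101071143523
g137	g433	0.8830717281019315
g137	g441	0.9827135787159205
g157	g346	0.9233741908660158
g159	g166	0.9113007934717461
g159	g191	0.9883909976156429
g159	g213	0.9409427371155471
g159	g263	0.8716043447004631
g159	g378	0.9074235663330182
g159	g434	0.9740326659660786
g159	g456	0.9876323401834816
g159	g468	0.9845228149043396
g161	g166	0.9856898820446804
g161	g191	0.9785479542380199
g161	g213	0.8870828222390265
g161	g220	0.9434476505964995
g161	g263	0.9384360528737307
g161	g289	0.9129168427269906
g161	g328	0.9565805766452103
g161	g434	0.9609789547044784
g161	g468	0.9246467320388183
g165	g169	0.886860956470482
g165	g280	0.876354099586606
g165	g289	0.9891567353531718
g165	g322	0.929219290688634
g165	g324	0.9977072631055489
g165	g378	0.9134847912937403
g165	g396	0.8838422349700704
g165	g408	0.9933165174350143
g165	g445	0.8833353473059833
g165	g456	0.8798937159636989
g166	g213	0.8919408107269555
g166	g220	0.872783341105096
g166	g263	0.9693559487722814
g166	g328	0.9078489532647654
g166	g361	0.9419842175301164
g166	g434	0.9823439772706479
g166	g449	0.8898923709010705
g166	g458	0.8859301453502849
g169	g195	0.8896237979410216
g169	g280	0.9516946380119771
g169	g289	0.9555014794925227
g169	g322	0.9056495341705159
g169	g324	0.9291711369063705
g169	g378	0.9350373018858954
g169	g445	0.903968247580342
g169	g456	0.9953914574254304
g188	g056	0.8861979585234075
g188	g225	0.971769728306681
g188	g234	0.9170022715302184
g188	g323	0.9071399997314438
g188	g433	0.9022833156818524
g188	g441	0.9321507151518017
g191	g263	0.8793892864184454
g191	g275	0.9921915847156197
g191	g328	0.8950202355813235
g191	g408	0.9494590648729354
g191	g434	0.9094572210684418
g195	g361	0.8811749796103686
g213	g044	0.8717656019376591
g213	g220	0.8873581563867629
g213	g263	0.9231206897785887
g213	g323	0.9684769003326074
g213	g328	0.9011544685717672
g213	g434	0.9318227967014536
g213	g468	0.961957111088559
g217	g346	0.9424348430847749
g220	g263	0.9985440014628694
g220	g328	0.9628524299012498
g220	g334	0.9278530475683511
g220	g434	0.9345303994230926
g220	g468	0.9119714240683242
g225	g044	0.8879224507464096
g225	g088	0.9187456109281629
g225	g234	0.8829789916891605
g225	g261	0.9392549640592187
g225	g321	0.9715083078527823
g225	g390	0.9898098325682804
g225	g433	0.9390045615751297
g225	g441	0.9512793993158266
g225	g468	0.8616382786538451
g234	g297	0.9725182366883383
g234	g321	0.9570275325421244
g234	g405	0.8684994872752577
g234	g433	0.9770475199166685
g234	g441	0.9637502737203613
g254	g346	0.9203278292762116
g261	g044	0.9534207911137491
g261	g321	0.9372740157321096
g261	g433	0.9232653124770149
g261	g441	0.8667856648610904
g263	g169	0.9771658565104008
g263	g275	0.8866721940273419
g263	g328	0.9893351432913915
g263	g434	0.9098004458565265
g263	g468	0.9526272651040927
g275	g408	0.8816322006983682
g280	g157	0.8996836609533057
g280	g322	0.9752740455744788
g280	g324	0.9261077559785917
g280	g396	0.9716512177791446
g280	g445	0.9584196184249595
g280	g456	0.9678850742336362
g289	g322	0.9320743220951409
g289	g324	0.902211087225005
g289	g361	0.9022409871499986
g289	g378	0.8972567118005828
g289	g396	0.9417586295586079
g289	g430	0.9649220288265496
g289	g445	0.9438257026299834
g289	g456	0.9439895475562662
g293	g135	0.9558656261768192
g293	g152	0.9737505964795128
g293	g323	0.9076676156045869
g297	g299	0.979691760665737
g313	g217	0.9570201494498178
g313	g390	0.9322959045367315
g321	g433	0.9811817947169765
g321	g441	0.9401128919934854
g321	g483	0.9489281349023804
g322	g324	0.9253473212663084
g322	g378	0.9709878633916378
g322	g396	0.9801340431999415
g322	g445	0.984335183063522
g322	g456	0.8674444918846711
g323	g217	0.8975487048691139
g324	g369	0.8901399849029258
g324	g378	0.8878293028054759
g324	g390	0.9856846415391192
g324	g396	0.9181418625405058
g324	g445	0.8684638557163998
g324	g456	0.8789594685425982
g328	g135	0.9554269943293184
g328	g157	0.864773349352181
g328	g434	0.8915228225337342
g328	g458	0.9229829264804721
g328	g468	0.8788555279048159
g331	g088	0.9930022420315072
g331	g449	0.8940968502871692
g378	g396	0.9719978487165645
g378	g445	0.9690172114828601
g378	g456	0.9317231815261766
g390	g254	0.9286603003647178
g390	g483	0.8927574150729924
g396	g157	0.8740305136283859
g396	g407	0.9574585153441876
g396	g430	0.995208316766657
g396	g445	0.948136709886603
g396	g456	0.8642305305367336
g396	g458	0.9617775932792574
g405	g346	0.9502969060279429
g407	g334	0.9215124683268369
g407	g449	0.866926486082375
g408	g217	0.9965228787949308
g433	g159	0.9899188655940816
g433	g213	0.8951547981845215
g433	g434	0.9917281097359956
g433	g441	0.8964499456668272
g434	g152	0.8889210204267874
g434	g334	0.879985550143756
g434	g396	0.880646635601297
g434	g468	0.9951650035660714
g441	g195	0.9002627531811594
g441	g217	0.9453624175023287
g441	g220	0.8614981528418139
g441	g331	0.9266098178271204
g445	g408	0.9170768465287983
g445	g456	0.9329539577569812
g456	g135	0.9211885024048387
g456	g152	0.9706641131918877
g456	g313	0.9979788555251434
g468	g299	0.9940363672561944
g468	g407	0.8637784388335421
g472	g297	0.8729824488935992
g472	g405	0.9554556013224647
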