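id,time,y1,y2,y3,y4,y5,y6,x1,x2,z1,z2
1,1,3.38761730922859,8.1863678339667,3.8335019098131,-1.26752980928395,-6.59673600039607,-0.657655016095195,1,NA,-0.0295950975269079,-0.700677461922169
1,2,8.84761143689517,13.6319505941923,7.4202878127366,0.762561603100891,0.183476056097208,0.925945217864242,1,0.528335760443483,-2.93849423713982,-2.57500370498747
1,3,NA,NA,NA,NA,NA,NA,0,NA,0.305910082999617,0.127226639539003
1,4,3.97822971063129,2.80756895583589,2.21228283900293,5.05232540222732,9.70316689596444,5.21481920227009,0,-0.108553157687597,-2.1567801469937,-1.29654460027814
1,5,5.41885200827757,8.08629078625255,4.30789028353497,NA,NA,NA,NA,NA,2.91766814282164,-0.304212431889027
1,6,2.74187445125764,1.75402690180586,0.641704263578566,0.676329914553235,-1.1463045707563,-0.332808489744658,1,-0.415923525031878,0.559638299513608,-1.36015107063577
1,7,NA,NA,NA,NA,NA,NA,0,NA,2.31822824757546,-0.746931531932205
1,8,5.36440530176926,8.34718570303684,5.48319377538582,7.45561962678782,9.52845258016786,5.02197470658688,0,-1.10848581600592,0.125605632551014,-1.95296024344862
1,9,6.33429124309354,9.82770646588827,5.5303848909526,NA,NA,NA,1,-0.703523793032906,-0.871203462593257,1.92386035295203
1,10,5.28918077780742,6.58397306016481,5.09391978728153,NA,NA,NA,NA,NA,2.85611390462145,0.278959386516362
1,11,5.79187237365337,3.64723590238517,3.57277959861807,3.62757478275649,7.16595102653049,5.58070450967298,0,-0.405359109901278,-0.725474594626576,-1.57059923931956
1,12,4.43674587498464,6.47817789477872,3.47046071731576,5.15754897459805,5.2657973733885,4.82115811017253,NA,0.40173442167169,1.76421811943874,-0.781796044204384
2,1,7.68435389688208,10.1303280563039,6.46431913951576,2.06815794783994,0.833640536168727,0.935806502936057,0,1.49254462012819,-2.1836702353321,2.05149897141382
2,2,5.09577052021579,7.38665839595556,5.69405788044208,0.911294846755803,0.723881680614937,0.995620044238895,0,-0.268679682239547,-1.06836002413183,0.426756762899458
2,3,6.38516496838653,8.28446553001972,6.31069781545522,NA,NA,NA,NA,NA,-0.334146545268595,2.62923888489604
2,4,4.68833360928409,9.67007648252518,5.53764765593407,-0.769533281625532,-2.80478408995648,-1.47082356205746,0,1.1964688009751,-1.42766947578639,-0.729535840451717
2,5,7.92343589274428,12.5656142365945,7.78437162088871,1.78280104547529,2.12576370490656,2.77481168134651,NA,0.230593632614913,1.5185450934805,-2.3636162658222
2,6,5.69117156706469,9.66799516772368,6.48876931711183,2.9965035597039,5.46989519188664,4.19656336011986,NA,-0.028650344958742,-2.34189498005435,1.62617587856948
2,7,6.25825937330737,7.00902519018399,4.96416733946634,NA,NA,NA,0,1.17625115265337,-1.03086426761001,1.86172050330788
2,8,3.65516308016092,5.27410982408099,2.69414790543361,3.01111496611465,-0.794846757765441,-1.41625657832734,1,0.0536853074127904,-0.974364386871457,-2.8708410426043
2,9,4.51838815009077,3.25118008591837,1.71433385965397,2.79750180670352,2.7407380935052,3.39129893090463,0,0.211152608126341,-1.5485812802799,0.19664044585079
2,10,2.54585205716657,3.06843101798092,4.11151661985038,2.14076146590486,0.17397426628052,1.35334600289615,1,1.56235126218412,2.6286720293574,-0.827094038017094
2,11,NA,NA,NA,NA,NA,NA,NA,NA,2.91734183952212,0.906795718241483
2,12,NA,NA,NA,2.65948980785403,0.741692198292581,1.426640774185,1,0.201044077297638,0.63807840552181,2.81858479231596
3,1,NA,NA,NA,4.43754053983449,3.55715641441728,2.3401682053274,NA,0.254413598102172,0.883461928926408,0.096358934417367
3,2,1.96429621954795,2.82057698137241,2.37740529522549,NA,NA,NA,NA,0.4647175838357,2.63579471502453,1.08494469802827
3,3,NA,NA,NA,3.16716579149455,1.52981258432005,2.0093440417735,1,1.2098051409626,2.50599177181721,-0.0453090760856867
3,4,3.76823292724357,5.46523998412318,4.32400618023785,-3.55287415818641,-10.0523490298424,-3.6006445608274,NA,NA,2.49189139064401,0.291654474567622
3,5,6.40841497168691,12.9098755482802,7.37962050656719,NA,NA,NA,NA,NA,0.125267418567091,2.03546090098098
3,6,2.1728925098765,0.92015796314325,2.20886337921789,-1.72604714664342,-6.65435015799688,-1.50495999421754,0,-1.25380551756824,-2.41814945451915,-1.46797682158649
3,7,3.95910292881527,4.81446708416443,3.08348578927786,-6.8152146198555,-14.0319437806399,-5.01890565235225,1,-0.583127378198691,-1.76970768347383,-0.393047181889415
3,8,6.66366705363891,9.87157560065109,4.98646415304071,1.558574841295,0.867082261195733,2.52746307544334,1,1.59853895244209,-1.62236304720864,1.1221383260563
3,9,5.76714583265982,5.72953477446041,5.7176482537913,-0.474091080726306,-0.943389715824045,2.01149528547085,NA,0.789967441259235,-1.99526625545695,-1.21680136257783
3,10,3.5719895576937,4.76670865033672,3.2942735235846,NA,NA,NA,0,NA,-1.3238502368331,1.73502783849835
3,11,NA,NA,NA,NA,NA,NA,0,-1.20388840404846,0.633459274191409,-0.861556612886488
3,12,NA,NA,NA,0.974347520969146,0.549476749357958,3.41483504121117,0,NA,-1.20133118983358,-0.274898410309106
4,1,6.39023233256835,6.55687755414035,3.83855275173979,2.0715420739021,3.54386019621823,0.625801125363104,1,-0.436221405658794,-1.34340760996565,-0.992559759411961
4,2,5.96052833109464,7.30338454463084,5.00973875155573,1.59316784494599,0.0771126805241793,0.716068894434376,NA,NA,1.88645374495536,1.3865226265043
4,3,2.53787038289682,3.8196220376877,2.89757032826532,-0.0594975445080279,0.42114107716109,0.25270724727276,1,-1.01653563029149,-0.673651558812708,-2.35111875180155
4,4,NA,NA,NA,2.1032224944564,0.70769417217832,2.73153792337219,0,-0.338663750189556,-1.566550754942,-1.43886557919905
4,5,NA,NA,NA,-0.78142133180986,-5.91071467152593,0.26610823783529,1,NA,-0.531095966231078,1.97048560157418
4,6,0.198261019525037,0.00774370179605632,1.51837992319036,1.90016208112715,8.78578641879851,4.25091998816804,1,-0.340019142165286,-0.951826108619571,-0.850599738769233
4,7,-0.262391286118045,-0.802342524162043,2.39576425057625,3.34778702815342,3.64398716904113,4.37767789374852,1,-1.04717160554241,-1.8112339284271,-0.202151786070317
4,8,NA,NA,NA,NA,NA,NA,NA,NA,2.67549550021067,-1.71538274735212
4,9,9.38091389835524,10.1057413038615,7.75329291807881,1.06465708334565,1.69756474220956,3.04334908929202,NA,0.619290962044284,0.193423320539296,1.24631513888016
4,10,5.63728159543864,5.72002717479484,4.31020117190773,1.12950362541066,-4.01775531223835,0.588652433525836,1,NA,-2.68504946166649,2.97770130867139
4,11,5.22730312549963,8.00146563556952,4.49211797650863,-2.10222592910104,-6.68558325257179,-1.31476995883961,0,2.11466950612186,-0.639593318570405,-1.64501638524234
4,12,7.13300409369817,5.90446502240211,3.70211796893975,-3.87855027282196,-10.1339149454073,-2.29571499228968,NA,-1.93704327466048,-0.201927466783673,-0.780966070946306
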