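"x","y","z"
0.767842979481289,-0.445096673944278,-1.3823006139568
-0.494147802018891,-0.827861215136693,0.796350314930983
0.970584052501008,-0.214354172854668,-0.328892034708365
0.48519210950072,0.540496487570103,2.06205467294725
0.582176924563679,-0.418667760136974,2.09095337493383
-0.733517095923839,-0.300142254577146,-1.82942769002857
-0.680881748693796,-0.655116266479105,0.982346423219128
0.387197477312404,-0.851965858223909,-1.05739803756834
0.844879008640749,-0.332431451207549,1.25738582744376
-0.284732388542044,0.495080876667189,2.46260056287298
0.229483489667603,0.779505984146374,1.74853359643152
-0.921218464989295,-0.0726981105862561,-1.14657913827158
0.285584372690272,-0.686658304476507,-2.00561149047291
-0.86495708423038,0.309909550200599,-1.18416545220982
0.997449674911165,0.0548466485466211,-0.137017956725894
-0.462634205642304,-0.2197786771382,2.57662615130831
0.327664860647086,0.548675855778239,-2.30744770242974
-0.0481280687756052,-0.551306245821552,-2.49874088509127
-0.607018935883163,-0.781199127955445,-0.437382447805499
0.0832963103550135,0.967045879808681,0.721772761495378
-0.213224750931459,0.92643263121082,-0.930763164699875
-0.239374423074537,0.730129772892004,1.92002437558215
-0.998560802655023,-0.0441567005283613,0.0913158408746074
-0.616217732965954,0.0335751849673693,2.36057952901281
-0.720599349036493,-0.693259741097287,0.0338760369160071
-0.692430947237568,-0.698952737797797,0.536693658145717
-0.62430919448471,0.747266431702379,-0.682992084576248
0.550380345490582,0.0273079137635038,-2.50340204088196
0.504597787795557,0.679053224156147,1.59950308590973
-0.522913609407743,0.58732839320721,-1.8532297322942
0.236164799759381,-0.953160097826438,0.566928688103687
0.944228298713551,0.293643025755255,-0.447057311766972
-0.601945761255025,-0.369058257458129,2.12440950101003
0.866085121873559,0.131244352473465,1.44708097027006
0.00588136134611283,0.982363283048841,-0.560669338697931
-0.922173596352984,0.175300422011569,1.03430681235682
0.68782251268306,-0.245810141410959,-2.04897488731145
-0.100080992077763,0.983113269757835,0.459618150922151
-0.778344375046529,-0.369824035321433,1.52206831337756
0.414103723416734,0.0433816218527447,2.72758597852394
-0.791229210925678,0.463136647041715,1.19797622576743
0.816731978770032,0.12561152597971,-1.68953708883792
0.77866828680639,-0.529586069004117,-1.00941995806944
0.0491115073836439,0.421010581492161,2.71717562020331
-0.254603116523404,-0.866818823655161,-1.28616539376663
-0.554917678729195,0.505878122749571,1.98125799753958
-0.555515148750616,0.822294281614581,0.370290838926484
-0.0590178038514654,0.392488545450358,-2.7535843485663
0.777957732380687,0.611585322948447,-0.432095399707374
-0.0552418232557436,-0.764613751511624,-1.9263507903973
-0.367111551736912,0.930114263163895,0.0323897262047221
0.819593950105202,0.554641723306468,0.430981254194719
0.444443328696897,0.681714736398227,-1.74344954380356
-0.400944057643052,-0.43995422424236,-2.4106342088563
-0.7404774628679,0.671492492591585,-0.0843720000990388
0.307925377415203,0.920759256687914,-0.718650943438487
0.0544839733045058,0.873972197929793,-1.44873629245922
-0.32334036986621,0.845614684402298,1.27415905468739
0.55307381118712,-0.773380510548973,0.929477007535783
-0.137173311643267,-0.966037532767085,-0.656958682660424
-0.229358663400155,-0.260433207426888,2.81356043687242
0.089867002259414,-0.935258162372483,-1.02710506988573
-0.817449812410489,0.0381664636199515,1.72420188122019
0.14604337583951,-0.841048376948185,1.56261980022525
0.417571310852195,-0.440242949621564,2.3846138284752
-0.0945506879443721,-0.482204049809001,2.61282506031563
-0.339072611994848,-0.923651411377382,0.535798942234919
0.971270791882076,-0.000870586901019946,-0.713926199433047
-0.984369771383167,0.0342878046978303,0.518232087702497
0.699432751099194,-0.692824875588663,0.526391172131819
0.928696461993579,-0.184124348601733,0.96570696983783
-0.118154622937929,-0.776230614144271,1.85783467205573
-0.558022257118873,0.0405460933001523,-2.48650448901716
0.45552863646993,0.88577867371351,-0.266473681536538
-0.531184835476261,-0.601791983164418,-1.78919024031316
-0.497485465688046,0.421442502544236,-2.27465378822923
-0.57477943102273,-0.676045271541647,1.38322903688952
0.952009024923515,-0.293950186058292,0.255829906821445
0.390719671682828,-0.918529320877274,-0.18104757286189
-0.930055664858854,0.31079294528612,-0.587909728460934
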