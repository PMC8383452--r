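area_id,x_km,y_km,population,phys_density,remoteness,nearest_centre,metastatic,high,intermediate,low
GA01,-2.2853423980996,-3.58563384972513,1348,0.623761936190329,-0.0628281158801118,A,1,10,2,1
GA02,54.4216363038868,0.835058139637113,4462,1.61574695243979,-0.108470477262764,A,4,19,12,3
GA03,125.482341186143,0.369197409600019,918,1.51385015111969,-0.0329736097414777,A,2,6,3,2
GA04,177.368311998434,2.26602725218982,2155,2.18133121717448,-0.0382606970605281,A,4,8,4,1
GA05,231.5411903942,-2.42427922319621,701,0.567653271090426,-0.00575731088047659,A,0,1,6,1
GA06,295.198025749996,-1.82734854985029,3955,0.583656436964143,0.0464031332313001,B,6,14,13,6
GA07,351.396653554402,6.49067651946098,6517,0.526511211682662,-0.0155680277939814,B,9,28,26,14
GA08,429.765189541504,-5.0319541618228,4911,0.966765654960875,0.0820038954381457,B,7,9,23,9
GA09,477.663644435816,-5.42041489388794,6754,0.904147440549005,0.0558838562686099,B,13,25,17,10
GA10,542.174998731352,-4.41369247157127,1504,1.71963159380346,0.0437815344282141,B,0,8,4,4
GA11,4.68959755264223,67.751016295515,366,0.749232710752784,0.16082314825901,A,0,2,0,1
GA12,59.9754835944623,57.008544979617,1017,0.682342078269758,0.0226940397657121,A,3,5,5,2
GA13,120.998467407189,62.6099851634353,3617,1.29647452723238,0.167645659298634,A,1,12,10,6
GA14,185.586891593412,62.2750048711896,1667,0.559975046687684,0.167043121969947,A,1,3,4,3
GA15,245.046434556134,57.6942272670567,1360,2.7333176782348,0.111021077341597,A,1,4,5,2
GA16,300.616099252366,50.5767061794177,3156,1.98859821984507,0.185115094958314,B,4,11,9,6
GA17,361.905066533946,59.334024572745,2713,0.849218275274863,0.123092735523252,B,2,13,14,2
GA18,411.802910477854,63.1913236435503,23779,1.64921421766245,0.14487504114129,B,25,80,83,42
GA19,471.657401085831,62.3302676063031,3187,0.554641971159167,0.218174177289729,B,5,13,11,4
GA20,545.432105786167,61.9082772824913,7410,1.93834957996107,0.177855274947321,B,12,31,18,11
GA21,-4.24395363777876,127.21642205026,1916,0.544141642580429,0.322816815516811,A,3,6,7,4
GA22,60.2618360798806,113.539305981249,4437,1.27537833981213,0.330112806068578,A,6,14,9,4
GA23,112.137793675065,124.47334268596,2577,1.59618467799949,0.240432853554646,A,1,7,5,5
GA24,182.287347367965,127.491884804331,160,1.31384446955289,0.201063844787183,A,0,0,0,0
GA25,246.623483165167,120.078383763321,1346,0.671958092488495,0.333886016582563,A,3,4,3,0
GA26,293.821836197749,121.29164068494,1862,0.659912279843951,0.230133611704032,B,5,6,5,0
GA27,354.79272483848,120.30941776,1027,0.737202162647953,0.272223207158562,B,2,4,5,2
GA28,415.078648016788,113.097033174708,2597,0.421446963450497,0.185007546882992,B,2,5,7,3
GA29,484.971932792105,125.797606632113,1291,0.566704148665905,0.24950164968696,B,3,7,4,2
GA30,532.360553755425,121.899225953966,1830,1.1439775669863,0.344253083155311,B,2,6,8,6
GA31,-8.50360405165702,174.783155266196,1302,2.36445670875191,0.37160048502746,A,3,7,1,1
GA32,68.6279278760776,180.987982875668,876,0.906052063632775,0.409722935650456,A,0,4,3,2
GA33,123.657023552805,185.667764823884,5837,1.09237357404945,0.467872248803404,A,4,20,17,9
GA34,179.056542585604,186.632236209698,2312,0.552889483834766,0.407337619210154,A,1,5,7,4
GA35,247.26661989931,178.722833283246,965,1.78076798031069,0.464537932089191,A,0,7,7,1
GA36,297.418155763298,176.240365323611,2054,1.43213885752828,0.336336939982284,B,2,9,6,6
GA37,369.353907713667,175.773635250516,2543,2.34507216445751,0.271329673262436,B,2,11,6,1
GA38,428.350146706216,187.492775265127,677,1.28692868188244,0.409196352895945,B,1,7,1,2
GA39,488.606009916402,187.451646430418,998,0.724296430684018,0.411780081173739,B,0,4,2,4
GA40,532.831830545329,189.64378063567,1551,0.567974198126942,0.353405412593192,B,0,8,8,3
GA41,7.28144212160259,242.481047674082,2628,1.25664274241971,0.614378378542399,A,5,8,9,7
GA42,50.6331934593618,245.52748973947,4115,1.24321477234494,0.546223740853555,A,8,12,20,3
GA43,122.805689307861,237.284475234337,1489,1.95124866003633,0.533934597730199,A,3,5,6,3
GA44,188.191204904579,249.003214687109,1564,0.76479554728466,0.539134872808222,A,2,5,6,2
GA45,242.672590487637,231.169964792207,3171,0.538563840403136,0.515763178296471,A,5,7,6,0
GA46,309.761553173885,246.260837106965,656,0.26388931531083,0.454974467165403,B,0,1,3,1
GA47,351.159398392774,247.221376155503,11405,1.66055961214871,0.543907091296323,B,20,38,41,19
GA48,428.624626295641,247.88755308371,691,1.01591782824315,0.60130965909656,B,0,4,4,2
GA49,486.540191983804,233.73318222817,4727,0.417011736512724,0.511015191472605,B,9,18,24,9
GA50,547.689750036225,235.865079262294,3056,1.44240206158518,0.432722565705844,B,5,11,9,8
GA51,0.13795614708215,303.9492748864,2099,0.326728004186116,0.611871677318318,A,3,5,7,2
GA52,56.4725969405845,308.612049189396,10823,1.07342710642141,0.655271073030525,A,14,35,28,18
GA53,126.010420755483,302.008315427229,404,0.854560584749579,0.648452197253292,A,1,2,2,0
GA54,178.241929472424,296.463720523752,1351,1.50269162576354,0.63980461554156,A,2,4,11,2
GA55,249.528674231842,307.826480600052,1459,2.18373522345401,0.666776324718021,A,2,5,5,2
GA56,296.545358984731,301.308703413233,860,1.88110436639971,0.738568673687143,B,1,3,4,0
GA57,351.317653213628,293.212092970498,1149,0.478754818948836,0.599599352503548,B,0,3,4,3
GA58,413.163626040332,296.309957946651,11058,1.31320463384364,0.580684305920517,B,14,38,33,17
GA59,486.789731713943,298.387735649012,3260,0.934675377214736,0.622750910986376,B,3,17,12,3
GA60,546.972977607511,302.374986037612,4532,1.7275893447916,0.63023590654766,B,8,16,19,9
GA61,9.0494375443086,350.069511877373,3396,2.31453962476774,0.720398969441989,A,3,14,13,3
GA62,62.1222482714802,358.290906050242,1566,0.614372310373923,0.689139816527819,A,2,8,4,2
GA63,125.751595976762,363.028340130113,3667,1.00515153639951,0.639493983699573,A,6,14,8,3
GA64,186.128986901604,362.51915877685,2715,0.71483599218619,0.799515883255168,A,5,8,9,1
GA65,243.263051239774,367.936951564625,1577,1.44885574513188,0.742316028976774,A,5,6,9,2
GA66,297.52058273647,368.086831560358,1558,1.38448338210203,0.741786843063856,B,3,1,6,2
GA67,362.205291208811,350.213135657832,1101,2.27600280824986,0.733668609143927,B,2,9,9,3
GA68,411.400040378794,358.204137654975,5069,0.562237417665228,0.744877055743379,B,4,21,20,5
GA69,481.181124793366,368.805636358447,1095,1.01526800809387,0.783127638641954,B,3,1,5,2
GA70,536.200756835751,357.922016135417,5363,0.491900779554809,0.820592786922161,B,13,12,20,8
GA71,2.58078255224973,426.605579266325,1990,2.66100209875433,0.865951345521195,A,4,6,10,3
GA72,63.8892252882943,413.273827121593,2043,0.909258749927734,0.834924694773774,A,3,5,6,3
GA73,129.951468482614,415.569997620769,903,1.13942453064977,0.798159340332992,A,0,3,8,1
GA74,173.543383767828,411.750423763879,918,0.775312967338818,0.859201624510326,A,1,4,4,2
GA75,244.362352048047,415.182428550906,1915,1.45407028087705,0.874862007327406,A,1,6,9,4
GA76,294.218238228932,428.375978399999,11763,2.03133763884207,0.842277430896622,B,21,41,40,18
GA77,355.796212828718,417.688511819579,1475,1.78966127072006,0.848404455525576,B,3,8,7,0
GA78,425.731180412695,428.711361852475,3884,0.428398925852248,0.876071543113841,B,4,10,9,6
GA79,484.250265369192,413.831621902063,656,0.570754652385859,0.723260098270976,B,0,1,5,1
GA80,537.62903994415,427.793305101804,255,1.4191870010671,0.918859267631303,B,0,1,0,0
GA81,-9.48636009823531,487.241396144964,1765,3.73426187562204,0.995539163165013,A,3,4,10,2
GA82,65.7581392861903,488.759287991561,2498,0.91706997888935,0.969650694581705,A,4,14,9,2
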