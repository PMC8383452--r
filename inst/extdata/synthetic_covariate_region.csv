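area_id,x_km,y_km,population,phys_density,remoteness,nearest_centre,metastatic,high,intermediate,low
GA01,5.91861337423325,-5.75212418101728,457,0.551761430807951,-0.00939947088669908,A,0,0,3,0
GA02,65.8093594061211,8.56102809309959,1144,0.235373645707461,0.0095071884448673,A,0,6,1,2
GA03,127.932205828838,-5.12065276503563,922,0.6516273279509,0.0549261310422518,A,0,2,3,1
GA04,173.507045004517,-1.16784096229821,293,1.44612679257889,-0.0382086894570806,A,1,0,0,1
GA05,243.686377536505,-6.88992531970143,1041,0.43081044012215,-0.0305872563046518,A,4,5,4,0
GA06,302.766798995435,2.2699297266081,1073,0.645246823114821,0.0913001452430426,B,3,3,6,2
GA07,353.745941617526,7.54655911587179,7430,0.41132903135104,0.0382365723060529,B,8,28,27,9
GA08,426.203043409623,9.30199827067554,12095,0.986363174343056,0.0940930508335434,B,15,41,47,19
GA09,474.649696308188,1.39571261126548,7643,1.64195994723759,-0.0778030178429412,B,3,30,26,7
GA10,538.608420165256,3.32510922569782,690,1.13545676687049,-0.0035623563414801,B,1,0,5,0
GA11,6.03093839716166,64.7221157420427,6138,1.98643161077654,0.0953209625523758,A,12,21,19,10
GA12,56.2330954056233,65.4363306146115,3889,0.883910558035454,0.174145609029332,A,3,16,13,6
GA13,116.513691013679,55.7068490656093,4603,1.07537284959459,0.0725880317112194,A,3,15,14,7
GA14,171.974554373883,65.7296338304877,830,0.315560725000324,0.110695241427385,A,0,1,2,2
GA15,246.015400043689,50.0500452565029,514,1.20990676946711,0.136449102363067,A,0,0,0,2
GA16,306.440373645164,61.2138821138069,6388,2.63487335417085,0.139982171180677,B,6,28,19,11
GA17,369.678341569379,53.9996903389692,1161,0.630738686119069,0.142269888478176,B,4,5,3,2
GA18,426.013313969597,51.3884416176006,8539,0.570688352242259,0.0996713393636976,B,14,23,24,9
GA19,472.398122842424,65.9733918262646,200,0.761750758777968,0.226997822048381,B,0,0,0,0
GA20,539.385874448344,54.6903704479337,1874,1.67293415907127,0.226075474328856,B,4,10,2,3
GA21,1.53184848371893,127.716389782727,1711,0.964238461183751,0.245069978625654,A,3,2,4,2
GA22,57.6029668143019,127.565676658414,3267,2.0254979504314,0.273239742599998,A,1,6,12,2
GA23,129.961354485713,129.934546304867,3480,0.673268680691944,0.360571580582946,A,4,16,10,6
GA24,179.625751590356,127.013399759308,1030,0.632400627902316,0.285523813677283,A,0,4,5,1
GA25,237.841154141352,118.265075846575,2017,1.34243290372638,0.241631402519177,A,2,3,8,1
GA26,309.555466882885,126.900569172576,2221,1.5784046117789,0.234285758906196,B,2,6,11,2
GA27,364.35336493887,112.321618464775,3116,1.36703197993574,0.16603438642583,B,3,14,16,3
GA28,421.306954575703,123.625129326247,2765,1.20981108162974,0.21960216864805,B,3,7,17,3
GA29,481.524525741115,124.465756686404,1618,0.656482826517023,0.28189509652465,B,0,5,2,5
GA30,543.633954031393,128.245273595676,577,1.32162443373807,0.308171587811954,B,0,0,2,0
GA31,6.58214060589671,170.036607966758,999,0.582567774443257,0.391482991790854,A,1,5,4,3
GA32,65.6531326472759,187.158614965156,12808,0.610059400108559,0.429371529050824,A,21,51,30,15
GA33,113.09716663789,186.389740542509,5738,0.762563946579189,0.375780435239419,A,7,24,20,8
GA34,181.646836129948,181.504389331676,6418,2.89031630854855,0.360141724244097,A,12,25,19,9
GA35,233.517198497429,186.004761643708,1499,0.781833778606155,0.335031365786926,A,3,5,6,6
GA36,300.832013655454,185.038244542666,2268,2.02579389814853,0.434752137577064,B,0,11,8,6
GA37,362.273537279107,176.228886418976,2766,1.35165583533607,0.36391046199136,B,4,12,13,4
GA38,426.938569853082,185.613318076357,4703,0.6981490851931,0.355646095544626,B,4,20,13,4
GA39,476.294004158117,180.890812170692,4089,2.084349122643,0.29070468311176,B,1,13,8,6
GA40,531.656534876674,177.183236586861,4562,0.312564021532759,0.340551002754032,B,5,14,26,10
GA41,-9.1513205319643,238.962229653262,5417,0.593733937633545,0.567965453149365,A,4,15,14,8
GA42,51.7734084418043,245.792281152681,8278,0.759790355169956,0.566938695969404,A,9,36,33,17
GA43,113.28490302898,242.830598792061,4476,0.988426795060631,0.485178882605802,A,5,21,19,3
GA44,180.65952914767,242.449671947397,1522,0.25399839814887,0.562853469163333,A,3,3,5,3
GA45,230.28590220958,233.232363932766,9124,1.83926852238356,0.563415030497306,A,13,37,25,10
GA46,303.490163073875,230.761493714526,8023,0.728995915531422,0.494997785464379,B,12,30,25,6
GA47,357.786602075212,238.334531793371,1631,0.86537974610475,0.526202429641265,B,2,5,9,3
GA48,412.331011421047,240.477569205686,8182,2.67161105414136,0.544450269442855,B,6,30,25,9
GA49,479.484464572743,247.167850863189,806,1.19941839205457,0.497858511318685,B,0,4,2,1
GA50,535.426378068514,246.096034883521,1629,1.64727660605238,0.448952404132241,B,4,0,6,1
GA51,9.34644441585988,295.04888296593,4385,1.12038427060166,0.616647991364189,A,6,14,11,8
GA52,58.7116966629401,302.160751377232,662,2.17376795079963,0.664848283660151,A,1,2,2,2
GA53,112.590522845276,297.986623249017,4517,1.02437641647112,0.626456713576212,A,6,14,15,4
GA54,178.873039660975,297.697950555012,717,0.424227434018514,0.723514805082077,A,1,4,0,2
GA55,231.436320794746,307.306667412631,5220,0.498767882993187,0.660532920921922,A,5,12,29,8
GA56,307.180598946288,293.81473257672,957,1.17542463574553,0.570742033583075,B,0,3,4,1
GA57,350.929367607459,297.674028519541,1090,0.481583668822524,0.608248735584714,B,2,4,4,2
GA58,414.331893962808,304.02948458679,3607,0.641915039723469,0.701654497560341,B,4,13,6,5
GA59,480.970811918378,292.490425221622,2209,0.672947598200789,0.680684731703235,B,2,6,13,5
GA60,546.647280184552,297.806093357503,2238,0.545172067647709,0.566800620972889,B,3,13,8,1
GA61,-5.76994060538709,350.541168707423,440,0.687917620448429,0.748564632648892,A,1,4,0,0
GA62,64.4779565231875,350.403722343035,4063,0.841455888365346,0.682993012794822,A,5,15,17,3
GA63,128.328595492058,361.363642346114,9777,2.79311223747813,0.718253727019214,A,11,40,33,9
GA64,189.858335531317,366.903439625166,6025,1.47529004829268,0.720798772294323,A,9,21,24,6
GA65,243.283611326478,359.823068659753,3466,0.47187239460189,0.702679038277573,A,7,6,15,4
GA66,294.708081753924,359.103855392896,2428,1.79595357870724,0.787192840059609,B,6,9,7,5
GA67,353.690177397802,356.070586103015,963,0.437862757224859,0.747117569071339,B,1,4,4,2
GA68,426.260538613424,352.442576056346,2211,1.83895600371639,0.809154581545266,B,1,6,4,3
GA69,473.434096765704,352.14322543703,16130,1.3612180835557,0.722655548571338,B,8,65,44,38
GA70,549.342440925539,362.801979193464,3587,0.465630394428543,0.756042429749187,B,2,16,10,8
GA71,6.27023072913289,420.727419285104,3226,0.968422226550918,0.854317491793653,A,4,13,12,4
GA72,53.7913576094434,411.196999191307,9763,0.655005352717892,0.854251546328887,A,2,31,34,15
GA73,119.591093300842,427.548955050297,3711,1.05082202986229,0.816847738484618,A,1,17,16,2
GA74,171.105338870548,421.68880472891,441,0.817351556260791,0.850462747043939,A,1,2,0,0
GA75,242.482622158714,418.111236067489,1787,3.97742046600917,0.948528227603557,A,4,3,4,1
GA76,291.024094764143,425.774050308391,6557,0.909530242877876,0.884870988105443,B,12,18,33,10
GA77,350.838724942878,422.793772020377,1715,0.617816260572481,0.918544021621164,B,1,10,5,2
GA78,416.166121340357,421.88500571996,1793,0.670355999801554,0.866668020813969,B,4,8,9,2
GA79,484.493373921141,420.605803919025,5277,0.939089346211402,0.852063497013834,B,7,21,21,8
GA80,531.720381616615,418.083919240162,1326,0.455464487844426,0.912531674717173,B,0,6,0,1
GA81,-2.65928883105516,470.085868365131,2166,0.591653657837628,1.00011759945397,A,0,12,11,2
GA82,68.6233758181334,478.410289934836,3413,1.07201688760199,0.996881118841136,A,2,14,12,4
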