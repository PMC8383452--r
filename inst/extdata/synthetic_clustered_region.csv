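area_id,x_km,y_km,population,phys_density,remoteness,nearest_centre,metastatic,high,intermediate,low
GA01,-8.65539391059428,9.14201812818646,1428,0.535579867918919,0.00451224842835088,A,4,3,3,3
GA02,67.414907598868,1.04931806679815,13098,1.36151808967946,0.0745680142081678,A,20,41,72,22
GA03,115.077391881496,6.11933828797191,788,0.445467887499704,0.0965432250394072,A,1,2,5,1
GA04,170.192981911823,2.48401957564056,4005,1.15703158398645,0.0572723691487416,A,7,14,19,2
GA05,238.602757989429,1.13200188148767,6547,0.651209289513913,-0.0939234961040155,A,10,30,26,11
GA06,294.610750344582,-5.38640411570668,3624,0.285367603320157,0.0334294149167651,B,9,11,9,3
GA07,355.483744246885,-9.05803834553808,1504,0.473881247346387,0.0299133582121904,B,2,2,9,1
GA08,424.618247826584,7.82859635073692,2367,3.0481485225414,0.114216414745911,B,5,8,9,4
GA09,480.553536261432,7.70387389697134,1001,0.920681638847772,-0.0921518588318884,B,2,8,6,3
GA10,530.652726432309,7.30870701838285,4546,1.15119484949651,0.0358156779893275,B,6,14,13,7
GA11,1.33136454503983,56.6258603194728,1937,0.995094430771718,0.0645179238258541,A,2,2,10,5
GA12,66.3925168989226,69.0718450769782,2447,0.620123543161017,0.201429423988058,A,1,10,5,6
GA13,121.698573371395,61.7574037471786,2058,1.10294307885164,0.191126097648034,A,1,8,9,1
GA14,187.779346844181,55.5340634007007,2081,0.806829869130402,0.0654924339946929,A,1,7,6,2
GA15,237.713976688683,61.9812088832259,1899,1.17900014657541,0.227461644582698,A,3,9,3,3
GA16,304.829633706249,61.5285837789997,2287,0.928838419557241,0.207019436436661,B,8,11,7,3
GA17,365.152786406688,63.2281269878149,4233,0.753852734878841,0.127573184299601,B,3,15,17,9
GA18,417.730298172683,66.8384529091418,5723,0.476606441462685,0.163631330856277,B,4,28,30,7
GA19,481.705899229273,64.9953969893977,2313,1.4752778875563,0.0135593298184109,B,1,7,10,7
GA20,549.089151625521,60.407824665308,4978,0.504760428048432,0.0793133359723233,B,6,17,22,5
GA21,-8.8139002583921,120.729857110418,2217,0.990210687742027,0.258592750102872,A,1,3,6,1
GA22,60.650626658462,122.1627393784,1619,2.35938324844115,0.316184021450667,A,2,8,4,2
GA23,121.523896069266,116.143226963468,1860,0.31708590520263,0.256977103887661,A,3,8,6,0
GA24,178.25722434558,128.819324122742,5370,1.42233795087787,0.264556127752076,A,4,25,14,7
GA25,236.175909363665,113.187734629028,1428,1.53373043684406,0.183829886227793,A,0,10,2,0
GA26,290.329947797582,110.884254598059,2948,0.425947159686839,0.25333009402227,B,4,15,12,2
GA27,353.940293691121,129.296590001322,2930,2.85346231049732,0.298254991564975,B,4,10,12,5
GA28,411.080330703408,114.68445058912,3274,3.17980413450886,0.276719850375653,B,7,9,15,7
GA29,483.154087015428,122.710505900905,2745,0.67944772678068,0.269322485520315,B,0,8,9,6
GA30,538.073693271726,118.342346698046,1267,2.37257426602948,0.300464685792248,B,0,5,5,3
GA31,4.43494911771268,174.34006031137,2627,0.643117807518935,0.378385005976938,A,9,21,19,3
GA32,66.5712443878874,174.670162578113,19332,0.731397405188829,0.325843818524436,A,85,215,142,74
GA33,121.355306655169,188.395519074984,6035,0.578288288371154,0.432824861586692,A,10,25,22,13
GA34,178.905576583929,185.400517741218,2692,0.317557320960758,0.294656927896618,A,5,10,9,1
GA35,240.58388851583,186.992953158915,4490,1.01394564529084,0.465879032799722,A,12,15,19,5
GA36,293.466381458566,181.996070495807,13282,0.511782660658653,0.404925028600279,B,21,31,48,30
GA37,358.730507595465,183.265227009542,3400,1.49016035019246,0.401476407753739,B,8,7,14,2
GA38,427.243988360278,176.997197857127,2277,0.76282282520118,0.431494774333894,B,0,11,6,7
GA39,482.944446643814,174.873418733478,4342,0.880204178908962,0.439621875023461,B,9,12,12,3
GA40,532.467933753505,187.275466606952,1403,0.250365969106262,0.470748659103846,B,4,5,8,0
GA41,-2.21509271301329,237.569603887387,1516,1.4502633867989,0.498753762679105,A,8,17,12,4
GA42,58.2540321862325,233.653246653266,1607,1.42013103407889,0.414091000134746,A,9,14,10,8
GA43,116.644742530771,243.937145033851,2531,0.737847876813881,0.480011409682302,A,2,14,9,3
GA44,187.51131077297,231.634911019355,4365,3.40774098616396,0.560068172448067,A,4,18,19,16
GA45,242.124489331618,233.069723499939,3811,3.70303760997436,0.490660830610695,A,3,12,8,5
GA46,294.464282444678,240.171162676997,9564,1.43434325739691,0.442982287164538,B,9,29,37,10
GA47,359.153263824992,237.560337698087,1864,0.30187403120724,0.517677751397382,B,1,2,5,2
GA48,426.303834808059,231.849710643291,2560,0.999377977650641,0.507877603391916,B,1,5,15,2
GA49,487.582528200001,245.879437290132,3164,0.61168503325427,0.499853698629699,B,3,9,13,4
GA50,544.461516360752,236.385070360266,1441,0.935232854857476,0.557023101309889,B,1,3,6,2
GA51,0.371733917854726,303.363039335236,1604,1.04182843691964,0.691066954082213,A,2,7,11,8
GA52,61.2219139561057,307.140833879821,1022,0.786850905327649,0.626103378944436,A,5,4,4,3
GA53,114.911142913625,302.541684764437,2461,0.602621565537386,0.703675227698219,A,2,8,5,8
GA54,181.583430930041,300.749997431412,17672,2.31472871711988,0.596155071624583,A,25,64,49,33
GA55,234.587139845826,295.50483812578,3001,0.979757039074227,0.633101646490872,A,1,9,15,0
GA56,290.226133787073,297.092664595693,1709,0.799368850047678,0.605898330754159,B,4,2,7,2
GA57,363.213966758922,305.176820941269,3188,0.363592835128079,0.723802216640035,B,6,8,12,5
GA58,416.944359405898,295.23034658283,12764,2.4665381522655,0.542910476454263,B,23,54,55,16
GA59,477.358760517091,295.987713644281,4066,0.509445887264686,0.64237999577066,B,4,13,18,5
GA60,549.391268435866,303.477214486338,2594,0.361472813233423,0.640568150041139,B,3,6,14,0
GA61,4.61921369191259,356.901800646447,1037,0.597483387269237,0.759316761366035,A,2,1,2,0
GA62,60.7126400433481,355.681311548688,665,0.714443942838946,0.794634732727253,A,1,4,0,0
GA63,126.104122092947,360.910015273839,2503,1.14922664635583,0.771443088815742,A,4,5,6,3
GA64,186.637364490889,367.29175449349,6212,2.14683969723355,0.756348259497005,A,8,26,15,7
GA65,246.43638108857,356.204500845633,205,0.658732799068977,0.738675051141145,A,0,0,0,0
GA66,293.908470585011,361.679170941934,13367,2.05311304427639,0.781963247843634,B,23,44,34,16
GA67,354.287808467634,367.899624132551,469,2.39730877639423,0.83209925231019,B,1,0,0,1
GA68,429.994887085631,365.448310351931,812,1.8663226590021,0.793334900039544,B,2,2,2,3
GA69,482.414128384553,368.124681599438,737,0.632081222969382,0.719081553370259,B,2,1,2,1
GA70,538.590705851093,364.672136940062,2659,0.418915854776492,0.865273512669349,B,3,7,18,6
GA71,-3.38531943038106,412.180661908351,410,1.02460086523802,0.833105435045604,A,0,2,3,2
GA72,51.2895817449316,426.925554373302,7511,1.10968461033762,0.962920711151478,A,11,27,22,18
GA73,123.841213695705,414.476390019991,4070,1.97289503483301,0.846185569966124,A,6,8,9,10
GA74,176.143553205766,415.826406972483,1821,1.6340696196104,0.859429481174206,A,1,4,10,6
GA75,243.549390952103,422.67438842915,3903,0.412018341064386,0.821565861085619,A,6,11,20,9
GA76,308.605442172848,424.667625827715,1076,0.493166135711053,0.920557658681097,B,1,5,2,2
GA77,361.213625688106,420.520895458758,1969,3.19670516666246,0.886013127007986,B,0,6,7,2
GA78,429.187095630914,411.851179986261,2563,0.914785728117478,0.869864722893742,B,4,11,3,3
GA79,485.496786623262,429.080643160269,951,2.51030220708971,0.843595229443346,B,1,2,7,0
GA80,536.657744152471,423.833099859767,8490,0.66261111871019,0.962582326346759,B,6,28,33,10
GA81,5.00971021130681,476.844963203184,3626,0.770585715473264,1.06508064319324,A,8,21,7,8
GA82,52.6963589759544,474.124490069225,594,2.31210667474033,1.0253484649455,A,1,6,2,1
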