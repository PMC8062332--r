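# semdis score run
# cleaning=stop composition=mult remove_cue=FALSE emit=per_space,mean,factor
# space space1: dim=50 vocab=69
# space space2: dim=50 vocab=69
# space space3: dim=50 vocab=69
# space space4: dim=50 vocab=69
# space space5: dim=50 vocab=69
# responses=30 oov_tokens=0 fully_missing_responses=0
id,item,response,word_count,space1_dis,space2_dis,space3_dis,space4_dis,space5_dis,semdis_mean,semdis_factor
p001,box,nababa,1,0.45269833116482516,0.42510773930802637,0.40812693598411076,0.43949471701457843,0.38086448279204044,0.4212584412527162,-1.3876400136642608
p002,box,nubaba mubaba,2,0.621836516900129,0.5837883984071048,0.5685722160614841,0.5908371551038061,0.6154508491282098,0.5960970271201468,0.1093082850756249
p003,box,subaba bubaba debaba,3,0.6703880068796584,0.6195990971428181,0.5529322951496752,0.6486064279757775,0.5006644887281253,0.5984380631752109,0.2115683648315419
p004,box,subaba bibaba kababa mobaba,4,0.47939157808004385,0.4335926055598983,0.46722115063681124,0.47982413124278733,0.457066119499699,0.46341911700384797,-1.0919570423764426
p005,box,pebaba gibaba pababa bobaba bababa,5,0.6842649144718503,0.6854899717889943,0.6210679752908552,0.7116629339285989,0.6561688571021096,0.6717309305164817,0.8323337735813865
p006,box,subaba bubaba kubaba gebaba fubaba mebaba,6,0.6664118300064316,0.6119879157193466,0.5915500136297442,0.48082942878954216,0.5476107282241052,0.5796779832738339,0.08693827957393749
p007,box,sebaba,1,0.47892478300151553,0.5142501373908925,0.5124450439091165,0.48084205666528446,0.4756493212528492,0.49242226844393167,-0.7101147337546788
p008,box,fobaba gobaba,2,0.5612979890020452,0.5814907245716332,0.4662892868921703,0.5474732582789662,0.6729810329844119,0.5659064583458454,-0.12036894629676713
p009,box,nababa bubaba kibaba,3,0.542552707122214,0.5440504422481672,0.491472811697408,0.5214171355859867,0.512917898240516,0.5224821989788584,-0.46044255398137585
p010,box,tababa mebaba pebaba mebaba,4,0.6688760392343931,0.6162649527856792,0.7266687192440894,0.7118190590894633,0.7144889830009133,0.6876235506709076,0.7969256009041014
p011,box,debaba rebaba bababa gebaba bebaba,5,0.4041817651913573,0.458806933213986,0.45653881591808587,0.41025934195768676,0.47456734249242605,0.4408708397547084,-1.179419709114637
p012,box,nababa gubaba fubaba bebaba gobaba bobaba,6,0.6709067557121569,0.6127072205641328,0.5704977646943548,0.44300053595661815,0.48433878202921865,0.5562902117912962,-0.058695466447845866
p013,box,tababa,1,0.5758170709880315,0.6122009540312545,0.5895408680964995,0.5645849797632603,0.5997802515133743,0.588384824878484,0.13401890751195364
p014,box,tababa gobaba,2,0.5479057293035406,0.5775026018720506,0.5996835260118898,0.5181827733102997,0.5937795038094307,0.5674108268614423,-0.07475656627820224
p015,box,sebaba rebaba dibaba,3,0.46856468312299115,0.5464445160680207,0.5383790777162212,0.5440527596439926,0.5659407879428457,0.5326763648988143,-0.38314901558607795
p016,box,debaba mibaba sobaba mebaba,4,0.5627529310851119,0.4959457971501422,0.5169558668147611,0.5366208374371849,0.5209503046771952,0.526645147432879,-0.5394441000735024
p017,box,tubaba bibaba tababa mubaba dababa,5,0.6854373239855117,0.8207448384009648,0.7409453350080507,0.8243186142222816,0.7669840406981844,0.7676860304629987,1.7743909857471074
p018,box,fibaba gebaba tubaba rubaba sibaba mibaba,6,0.8823383598524259,0.790449532261488,0.7874491040767254,0.71252429313647625,0.8423599409575013,0.8030242460569234,1.9396812701080672
p019,box,fobaba,1,0.501529793365473,0.5527803246724935,0.5313866348636208,0.5072127493985945,0.6011200152415179,0.5388059035083399,-0.33326351173751423
p020,box,tababa mebaba,2,0.6191727744787259,0.5627877819486855,0.6017795409730365,0.5787463307385605,0.5922954915692715,0.590956383941656,0.03978319067302907
p021,box,fubaba mobaba tababa,3,0.7782752929052892,0.7679888019231955,0.8214262468308297,0.7582553646612925,0.8768513745023931,0.8005594161646,1.8761502705389081
p022,box,subaba rababa bebaba bibaba,4,0.48024737217079205,0.36510925895043966,0.4288325637378859,0.5279357420839788,0.35933988729510535,0.43229296484764035,-1.4516196194455477
p023,box,pababa gibaba bebaba gobaba kababa,5,0.6305047611888128,0.5930693915929013,0.60954548222395,0.6266790993975531,0.6697427980548567,0.6259083064916148,0.3254086187872906
p024,box,libaba robaba nubaba gebaba mobaba mababa,6,0.46073148910691475,0.6210584540786062,0.6954573814376124,0.57704406685708,0.388622752423451,0.5485828287807328,-0.0505618727658623
p025,box,kobaba,1,0.4861569721742126,0.4610138100725327,0.4316190313478818,0.47758558356595093,0.4828707111373922,0.4678492216595941,-1.0124730237758264
p026,box,tobaba bobaba,2,0.38260296367403857,0.41004933739413996,0.37129127744270995,0.4506748300829385,0.3846622902326795,0.3998561397653013,-1.5698334965958372
p027,box,tababa bebaba fubaba,3,0.8691950040854657,0.793938485766159,0.7970631126350163,0.7481580676755661,0.8270171143639582,0.8070743569052331,1.9762733266744983
p028,box,nababa bobaba ribaba rababa,4,0.5272261827943812,0.48069739350717433,0.553131525888986,0.5361745182626814,0.541177556040825,0.5276814352988095,-0.5601472695928447
p029,box,kebaba mebaba subaba mibaba tobaba,5,0.6342611404778008,0.5898336123382951,0.6606888804811684,0.6066328072243994,0.6158803400321751,0.6214593561107677,0.3095256585922218
p030,box,kebaba mababa febaba bababa lababa bubaba,6,0.5994424321837819,0.623905362481187,0.7667771584441206,0.5668504517242389,0.6745806002809261,0.6463112010228509,0.5715804088875601
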