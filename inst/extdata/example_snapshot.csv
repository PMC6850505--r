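event,species,x_nm,y_nm,z_nm
1,e_aq,17.2546512074769,47.9354907386005,28.974143830128
1,e_aq,47.2983081266284,7.3139555985108,53.4210133273154
1,e_aq,24.538615308702,33.6568790255114,54.866291214712
1,e_aq,52.9810442402959,12.3918833769858,36.5240989392623
1,e_aq,56.4280370576307,7.65189901459962,24.6413865918294
1,e_aq,2.73338996339589,45.1984718581662,8.82568145636469
1,e_aq,31.6863292828202,53.702721549198,56.1179881962016
1,e_aq,53.5451426636428,22.4677665531635,18.0737339984626
1,e_aq,33.0861008679494,39.9069116776809,3.64323429297656
1,e_aq,27.3968841182068,5.69043965544552,56.863616402261
1,e_aq,57.4100007209927,23.0381782678887,43.2357764057815
1,e_aq,27.2000493714586,16.4630186744034,8.53765773586929
1,e_aq,40.654238127172,48.8784023327753,32.9570793639868
1,e_aq,34.3580041173846,26.9109804835171,57.2454743133858
1,e_aq,6.17548095993698,48.6038611829281,35.1290011871606
1,e_aq,53.9894982241094,48.7433705711737,24.2706169048324
1,e_aq,14.7652640612796,47.6605392666534,38.8736087596044
1,e_aq,2.52357201185077,26.3899012561888,19.1892370255664
1,e_aq,19.6752431569621,45.2685095183551,18.4632006520405
1,e_aq,57.2702189488336,37.7532678935677,13.1860578758642
1,e_aq,53.3723589638248,42.6109440810978,22.1693319501355
1,e_aq,41.568204369396,0.0374863995239139,59.0531522082165
1,e_aq,38.4304088260978,28.5189944459125,9.25213804934174
1,e_aq,59.6561865974218,13.2071331096813,5.46263999305665
1,e_aq,39.3423479469493,22.7889922633767,8.51441446691751
1,e_aq,42.5118280900642,36.7662601964548,41.400426090695
1,OH,32.6439614826813,21.1078745545819,37.1553890034556
1,OH,35.6485212268308,6.66812546085566,53.4836470289156
1,OH,17.3495842376724,14.6171683631837,40.3799455566332
1,OH,8.82681883871555,40.0833352468908,44.2246642755345
1,OH,57.7814539521933,25.0588067807257,31.2681435467675
1,OH,54.1379427071661,47.291750041768,39.5903069805354
1,OH,41.442316705361,6.17187865544111,49.3083276087418
1,OH,47.7280450612307,26.0935644898564,47.1768931020051
1,OH,1.47682107053697,59.0974187990651,58.7893150420859
1,OH,28.6677582655102,53.5830668639392,26.3658921746537
1,OH,45.507572251372,53.1881436472759,18.7021321244538
1,OH,12.9844761500135,10.5031590163708,24.5684971567243
1,OH,19.0908604580909,7.8417414939031,0.628026709891856
1,OH,13.8975471211597,39.1861155023798,11.0309714404866
1,OH,8.56800134293735,20.6109883356839,50.5637591332197
1,OH,24.8727801488712,39.4054876780137,13.8697069231421
1,OH,24.8234595777467,19.2223945492879,14.3459973391145
1,OH,22.1307270554826,11.2614671560004,4.60146992001683
1,OH,9.14668486453593,46.9376580789685,14.7434206819162
1,OH,8.32836380694062,5.6156992027536,43.9281123317778
1,OH,13.9820459671319,28.0067424941808,50.8471899060532
1,OH,27.9577470151708,30.6903275940567,29.8516360251233
1,OH,15.9583584219217,35.9993375558406,23.2745417905971
1,OH,51.4696629205719,19.9694124190137,14.7869396489114
1,OH,2.7498700004071,29.3167820200324,6.66578767821193
1,OH,26.5320044523105,57.2684296499938,23.3996661147103
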