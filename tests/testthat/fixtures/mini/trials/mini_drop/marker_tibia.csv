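frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.999796416458,0.0195914903276,-0.00482691874205,-2.62270220417,-0.0144750683183,0.529759412631,-0.848024431916,-2.93550716716,-0.0140569568179,0.847921658077,0.529935150494,-3.60054350039,0,0,0,1
2,0.9997834777,0.0206483134122,-0.00257776471442,-2.49813867999,-0.0131807489765,0.532554415539,-0.846293130273,-2.84648504935,-0.0161017258116,0.846143865807,0.532711265868,-11.810520006,0,0,0,1
3,0.999757525346,0.0217303232935,-0.00356139911782,-2.47977485952,-0.014558382347,0.530931626178,-0.847289597379,-2.81565178766,-0.0165210174492,0.847135999338,0.531119247071,-20.2191283613,0,0,0,1
4,0.999711745984,0.0222306856626,-0.0090676103056,-2.67629746436,-0.0194306971657,0.527318720135,-0.849445357514,-3.04170795935,-0.0141022320694,0.849376691468,0.527598676117,-28.648985187,0,0,0,1
5,0.999809947423,0.0189963835545,-0.00438251588693,-2.51344188253,-0.0137924336973,0.530360341707,-0.847660118631,-2.96159843537,-0.013778164114,0.847559464201,0.530521551718,-36.8480418884,0,0,0,1
6,0.999734614107,0.0219796867916,-0.00689889303134,-2.53577783768,-0.017477290826,0.528552555753,-0.848720649043,-3.08036852443,-0.0150081864959,0.848615984515,0.52879643074,-45.2398395272,0,0,0,1
7,0.999826277477,0.0186126245877,-0.000992507894604,-2.31074743575,-0.0107378226044,0.531650238568,-0.846895933983,-2.8762580161,-0.0152352890251,0.846759466458,0.531757738008,-53.4944492458,0,0,0,1
8,0.999692825617,0.0243064196453,-0.00484276514749,-2.37210465632,-0.0170527993188,0.532789910962,-0.846075713405,-2.85893186492,-0.01798489493,0.845898403321,0.533040744046,-61.7830231945,0,0,0,1
9,0.9996758528,0.0244192780923,-0.00720334552971,-2.35747159766,-0.0189783092035,0.52614068697,-0.850185745173,-3.01181273269,-0.016970948976,0.850046867162,0.526433576549,-70.3191071781,0,0,0,1
10,0.999660705871,0.0248384764283,-0.00784367429094,-2.38180401618,-0.019831935989,0.530562762837,-0.84741362333,-2.91423074581,-0.0168869018055,0.847281656109,0.530875341081,-78.4444887361,0,0,0,1
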