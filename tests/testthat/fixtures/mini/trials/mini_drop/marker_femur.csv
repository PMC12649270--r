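frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.997795756866,-0.0508804425721,-0.0426005650547,-4.12177780149,0.0507539824159,0.998702992355,-0.00404553203215,-0.0432439230799,0.0427511502564,0.00187446636626,0.99908399323,37.469131326,0,0,0,1
2,0.997839323729,-0.0509579524348,-0.0414725343222,-4.14799009858,0.050801569723,0.998697151574,-0.00481663281977,-0.176466481355,0.0416639476423,0.00269935579157,0.999128034311,29.0747810827,0,0,0,1
3,0.997915558881,-0.0492846229078,-0.0416600922753,-4.17202105446,0.0490893115686,0.99877813464,-0.00569888188684,-0.0395104600613,0.0418900564964,0.00364193765343,0.999115588637,20.7887954095,0,0,0,1
4,0.997879074965,-0.0510492483799,-0.0403896767476,-4.13602882644,0.0508494279131,0.998688547507,-0.00595992953639,0.0168527985835,0.0406409575285,0.00389349701642,0.999166229039,12.5081677469,0,0,0,1
5,0.997808390958,-0.0504093682397,-0.0428638603923,-4.0015348925,0.0501695033973,0.998718550989,-0.0066540843961,0.114515961093,0.0431443607314,0.004489042655,0.999058763353,4.14294731544,0,0,0,1
6,0.997876750013,-0.0503774605431,-0.0412807855162,-3.9655690726,0.0501580776666,0.998721208301,-0.00633366668577,-0.0152101582732,0.0415470700339,0.004249653882,0.999127510087,-4.17225836859,0,0,0,1
7,0.99792811725,-0.0501040617973,-0.0403615633272,-3.90517732246,0.0498418034543,0.998729124889,-0.00747861792082,0.164087396136,0.0406849779554,0.00545142999489,0.999157152044,-12.4383318898,0,0,0,1
8,0.997956512381,-0.0486959752257,-0.0413702960251,-3.75788057534,0.048644964531,0.998813622531,-0.00223939102534,-0.11676641412,0.0414302645679,0.000222358274728,0.999141373247,-20.8029169771,0,0,0,1
9,0.998086184921,-0.0480370984298,-0.038941040609,-3.73830593107,0.0479487817712,0.998844672087,-0.00319927658666,-0.101061030381,0.0390497349022,0.00132597830478,0.999236388441,-29.1243211952,0,0,0,1
10,0.998120144374,-0.0486758910414,-0.0372402339752,-3.71188344955,0.0485144362075,0.998808802022,-0.00522747378226,-0.0895580216747,0.0374503254281,0.00341095793071,0.999292669087,-37.4331089299,0,0,0,1
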