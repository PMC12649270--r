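frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.997897157351,0.06436667495,0.00762853240474,-28.610151363,-0.027769558034,0.53090151573,-0.846978413091,-3.02290310889,-0.0585671836216,0.844985509788,0.531572547496,-39.7674269407,0,0,0,1
2,0.997881388826,0.064664865802,0.0071546464523,-25.6355972371,-0.02833377586,0.530941569853,-0.846934617634,-3.02641797023,-0.0585656126115,0.844937574341,0.531648910924,-39.8050272505,0,0,0,1
3,0.997863631922,0.0649937539486,0.00663204604018,-22.6612237101,-0.0289560176313,0.530985545178,-0.846886001688,-3.03029320885,-0.0585638209985,0.844884703826,0.531733124895,-39.8457918558,0,0,0,1
4,0.997843825502,0.0653525159355,0.00606205981555,-19.6870266058,-0.029634708191,0.531033273125,-0.846832596742,-3.03451869967,-0.058561796239,0.844827030519,0.531824975463,-39.889617675,0,0,0,1
5,0.997821907307,0.0657402532115,0.00544613674319,-16.7130013412,-0.0303681294583,0.531084572207,-0.846774440968,-3.03908341205,-0.0585595253648,0.84476469876,0.531924229301,-39.9363938873,0,0,0,1
6,0.997797815256,0.0661559943055,0.00478584237636,-13.7391429309,-0.0311544247775,0.531139249104,-0.846711580101,-3.0439754411,-0.0585569951977,0.844697864611,0.532030634301,-39.9860022138,0,0,0,1
7,0.997771488784,0.0665986971851,0.00408285482706,-10.765445992,-0.031991603621,0.531197099794,-0.846644068348,-3.04918204133,-0.0585541925745,0.844626695472,0.532143920221,-40.0383172175,0,0,0,1
8,0.997742870223,0.0670672517937,0.00333896044608,-7.79190475035,-0.0328775466353,0.531257910727,-0.846571969308,-3.05468966266,-0.0585511045776,0.844551369679,0.532263799375,-40.0932066215,0,0,0,1
9,0.997711906204,0.0675604827576,0.00255604922417,-4.81851304715,-0.0338100110166,0.531321460049,-0.846495356896,-3.06048398846,-0.0585477187697,0.84447207607,0.532389967379,-40.1505316444,0,0,0,1
10,0.997678549064,0.0680771522614,0.0017361099263,-1.84526434649,-0.0347866362034,0.531387518848,-0.84641431625,-3.06654997569,-0.0585440234298,0.844389013519,0.532522103925,-40.2101473517,0,0,0,1
11,0.997642758232,0.0686159630822,0.000881224971771,1.12784825597,-0.0358049498727,0.531455852424,-0.846328944613,-3.07287189688,-0.0585400077875,0.844302390459,0.532659873609,-40.2719030242,0,0,0,1
12,0.997604501599,0.0691755617784,-6.43492617068e-06,4.10083202349,-0.0368623742226,0.53152622156,-0.84623935217,-3.07943338383,-0.0585356622533,0.844212424362,0.532802926792,-40.3356425389,0,0,0,1
13,0.997563756835,0.0697545420254,-0.000924616347029,7.07369456752,-0.0379562325277,0.531598383805,-0.846145662843,-3.08621747296,-0.0585309786427,0.844119341209,0.532950900493,-40.4012047654,0,0,0,1
14,0.997520512647,0.0703514480906,-0.00187098896112,10.0464438359,-0.0390837559494,0.531672094737,-0.846048015008,-3.09320665197,-0.0585259503898,0.844023374931,0.533103419331,-40.4684239737,0,0,0,1
15,0.997474769962,0.0709647784394,-0.0028431515234,13.0190881002,-0.0402420905834,0.531747109207,-0.84594656214,-3.10038290791,-0.0585205727502,0.843924766831,0.533260096476,-40.5371302543,0,0,0,1
16,0.997426543018,0.071592989465,-0.00383863804697,15.9916359409,-0.0414283047272,0.531823182553,-0.845841473367,-3.10772777623,-0.058514842989,0.843823764988,0.533420534655,-40.6071499483,0,0,0,1
17,0.997375860354,0.0722344993328,-0.00485492413951,18.9640962328,-0.0426393963469,0.531900071779,-0.845732933923,-3.11522239094,-0.0585087605528,0.843720623636,0.53358432716,-40.6783060872,0,0,0,1
18,0.997322765677,0.0728876919286,-0.00588943348543,21.9364781278,-0.043872300726,0.531977536679,-0.845621145489,-3.12284753538,-0.0585023272227,0.843615602531,0.533751058899,-40.7504188407,0,0,0,1
19,0.997267318605,0.0735509209042,-0.00693954445627,24.9087910371,-0.0451238982737,0.532055340914,-0.845506326416,-3.13058369379,-0.0584955472467,0.843508966306,0.533920307456,-40.8233059719,0,0,0,1
20,0.997209595265,0.074222513807,-0.00800259683122,27.8810446122,-0.0463910224742,0.532133253015,-0.845388711818,-3.13841110324,-0.0584884274508,0.843400983803,0.534091644172,-40.8967832988,0,0,0,1
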