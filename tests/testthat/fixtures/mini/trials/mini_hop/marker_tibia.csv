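frame_index,m11,m12,m13,m14,m21,m22,m23,m24,m31,m32,m33,m34,m41,m42,m43,m44
1,0.998004458044,0.0620377974384,0.0117649230426,-28.4649917488,-0.0229873034652,0.530495104533,-0.847376261142,-3.02786669134,-0.0588105909221,0.845414842403,0.53086256097,-39.7766877472,0,0,0,1
2,0.997854346039,0.0650806238807,0.0071565695137,-25.6443521976,-0.0285805896305,0.531320243583,-0.846688814533,-3.03385511185,-0.0589054665399,0.844667574348,0.532040256801,-39.7924973749,0,0,0,1
3,0.997809764586,0.0656520171922,0.00809236282473,-22.584860284,-0.0279415208291,0.529198547895,-0.84803783425,-3.15998337443,-0.0599578611297,0.845954318829,0.5298738957,-39.9159365254,0,0,0,1
4,0.997956005336,0.0634712904184,0.00743012154215,-19.6446319797,-0.0275219123015,0.531809518528,-0.846416670645,-2.99523029633,-0.0576745676775,0.844482108334,0.532469353998,-39.8452046273,0,0,0,1
5,0.997849501484,0.0653083776249,0.00558463968671,-16.7491843111,-0.0300244245669,0.53115118765,-0.846744914237,-2.96107501048,-0.0582658246132,0.844756314963,0.531969794267,-39.8975652643,0,0,0,1
6,0.997643306158,0.0683702793228,0.00577395733059,-13.643367106,-0.0315624189493,0.53200993708,-0.846149656123,-2.96940935324,-0.0609232910142,0.843973300379,0.532914083937,-39.9022982289,0,0,0,1
7,0.997867549917,0.0647882956381,0.00792651063302,-10.6631691208,-0.0277040137846,0.530361503778,-0.847318808319,-3.12181154516,-0.0591002575521,0.845292347096,0.531025430181,-40.0980675429,0,0,0,1
8,0.997783597907,0.0663120482658,0.00553208845679,-7.72940047843,-0.0308000608946,0.53393341958,-0.844965360062,-2.95122004906,-0.0589851506465,0.842922188408,0.534792423556,-40.0189835692,0,0,0,1
9,0.997677058055,0.0681017063563,0.00162647564529,-4.83239720465,-0.0347581008785,0.529443619384,-0.847632779166,-3.18234007583,-0.0585863657772,0.845607244224,0.530580838572,-40.203184247,0,0,0,1
10,0.997833123975,0.0657362766228,0.0027926035245,-1.85413366576,-0.0327470749855,0.532996662845,-0.845483404022,-2.96275085054,-0.057067379286,0.843559896707,0.533994395934,-40.1298979265,0,0,0,1
11,0.997637256215,0.0686662286744,0.00220319141198,1.15126024621,-0.0347396871393,0.531873545023,-0.846110918404,-3.06598218651,-0.0592710650337,0.844035236909,0.533002307411,-40.2543103259,0,0,0,1
12,0.997566054793,0.0697046443326,-0.00179690916371,4.05727542043,-0.0388003151664,0.533503262567,-0.844907571497,-3.00367452589,-0.0579353248638,0.842920833405,0.534909307027,-40.2516447937,0,0,0,1
13,0.997217449352,0.0743009158491,-0.0060607435441,6.93193506864,-0.044788846854,0.532161964404,-0.845457037844,-3.08078021053,-0.0595929350327,0.843375964529,0.534009049126,-40.3952645073,0,0,0,1
14,0.997524450357,0.0703007833444,-0.00166457241538,10.0657714381,-0.0388459715127,0.531159719516,-0.846380731622,-3.10425132198,-0.0586170746233,0.844350136036,0.532575709489,-40.4779956163,0,0,0,1
15,0.997545352302,0.0700154159713,-0.00105433691387,13.07988255,-0.0382885698516,0.532786469805,-0.845383086542,-3.06561970351,-0.058628112017,0.843348337948,0.534159456868,-40.521274308,0,0,0,1
16,0.997434663905,0.0714593764839,-0.00420104195361,15.9592511005,-0.0418301160924,0.534231603062,-0.844302573535,-3.07417632424,-0.0580890060912,0.842312383741,0.535850273461,-40.5599281721,0,0,0,1
17,0.997391091364,0.0720473654863,-0.00449310516355,18.9667777461,-0.042242645445,0.53205006803,-0.845658491364,-3.06444627967,-0.058536909496,0.843642046271,0.533705469328,-40.6546964089,0,0,0,1
18,0.997247940453,0.073965291347,-0.00506763638752,21.9823832631,-0.0435775919826,0.529497057426,-0.847191749047,-3.2343095874,-0.0599794859898,0.845081062297,0.531263079281,-40.8233522141,0,0,0,1
19,0.997300061442,0.0733006644771,-0.0044271926418,24.9846683542,-0.0430461289848,0.534696244798,-0.843947247509,-3.01800255853,-0.0594946907455,0.8418592153,0.536407907648,-40.7190474548,0,0,0,1
20,0.997096818709,0.0756599423194,-0.00857363681432,27.8708751094,-0.0474875454688,0.529870488176,-0.846748013747,-3.23510486981,-0.0595219887549,0.844696891724,0.53192508304,-40.965214741,0,0,0,1
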